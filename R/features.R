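#' Amino-acid composition features
#'
#' Frequency of each of the 20 standard amino acids in the sequence, in fixed
#' alphabetical order (ACDEFGHIKLMNPQRSTVWY). These are the first 20 entries
#' of the 188-dimensional vector.
#'
#' @param sequence character scalar, a sanitized sequence
#' @return numeric vector of length 20 summing to 1
#' @examples
#' amino_acid_composition("ACDK")
#' @export
amino_acid_composition <- function(sequence) {
  idx <- seq_to_int(sequence)
  tabulate(idx, nbins = 20L) / length(idx)
}

#' Per-class composition under a property scheme
#'
#' Fraction of residues falling into each of the scheme's three
#' physicochemical classes.
#'
#' @param sequence character scalar, a sanitized sequence
#' @param scheme a `property_scheme` (one element of [property_schemes()])
#' @return numeric vector of length 3 summing to 1
#' @export
class_composition <- function(sequence, scheme) {
  cls <- class_index(sequence, scheme)
  tabulate(cls, nbins = 3L) / length(cls)
}

#' Per-class distribution descriptors under a property scheme
#'
#' For each class, the normalized chain positions of the first occurrence and
#' of the 25%, 50%, 75% and 100% occurrence percentiles. With m occurrences of
#' class i at positions p_1 < ... < p_m, the five entries are p_1/L and
#' p_r/L for r = ceiling(q m), q in {0.25, 0.5, 0.75, 1}; a class with no
#' occurrence contributes five zeros.
#'
#' @inheritParams class_composition
#' @return numeric vector of length 15 (class 1 entries, then class 2, then
#'   class 3), each in \[0, 1\]
#' @export
class_distribution <- function(sequence, scheme) {
  cls <- class_index(sequence, scheme)
  L <- length(cls)
  out <- numeric(15L)
  for (i in 1:3) {
    pos <- which(cls == i)
    m <- length(pos)
    if (m > 0L) {
      r <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * m))
      out[(i - 1L) * 5L + 1:5] <- pos[r] / L
    }
  }
  out
}

#' Between-class transition frequencies under a property scheme
#'
#' Frequencies of adjacent residue pairs whose classes differ: pairs {1,2} in
#' either order, then {1,3}, then {2,3}, each divided by L - 1 (the number of
#' adjacent pairs).
#'
#' @inheritParams class_composition
#' @return numeric vector of length 3; the entries sum to at most 1
#' @export
class_transition <- function(sequence, scheme) {
  cls <- class_index(sequence, scheme)
  L <- length(cls)
  if (L < 2L) stop_validation("transition features require length >= 2")
  a <- cls[-L]
  b <- cls[-1L]
  key <- a + b           # unordered pair {1,2} -> 3, {1,3} -> 4, {2,3} -> 5
  key <- key[a != b]     # same-class pairs (keys 2, 4, 6) are excluded
  c(sum(key == 3L), sum(key == 4L), sum(key == 5L)) / (L - 1L)
}

#' Encode one sequence into the 188-dimensional feature vector
#'
#' Concatenates the 20 amino-acid composition frequencies with, for each of
#' the eight physicochemical schemes in their frozen order, 3 class
#' composition + 15 distribution + 3 transition descriptors (21 per scheme,
#' 168 in total).
#'
#' @param sequence character scalar, a sanitized sequence (length >= 2, only
#'   the 20 canonical letters)
#' @param schemes list of property schemes; default [property_schemes()]
#' @return named numeric vector of length 188 (names from [feature_names()])
#' @examples
#' v <- encode_sequence("MKVACDEKLW")
#' length(v)
#' sum(v[1:20])
#' @export
encode_sequence <- function(sequence, schemes = property_schemes()) {
  idx <- seq_to_int(sequence)
  L <- length(idx)
  if (L < 2L) stop_validation("encode_sequence requires length >= 2")
  luts <- scheme_lookup(schemes)
  out <- numeric(20L + 21L * length(schemes))
  out[1:20] <- tabulate(idx, nbins = 20L) / L
  off <- 20L
  for (lut in luts) {
    cls <- lut[idx]
    out[off + 1:3] <- tabulate(cls, nbins = 3L) / L
    for (i in 1:3) {
      pos <- which(cls == i)
      m <- length(pos)
      if (m > 0L) {
        r <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * m))
        out[off + 3L + (i - 1L) * 5L + 1:5] <- pos[r] / L
      }
    }
    a <- cls[-L]
    b <- cls[-1L]
    key <- (a + b)[a != b]
    out[off + 18L + 1:3] <-
      c(sum(key == 3L), sum(key == 4L), sum(key == 5L)) / (L - 1L)
    off <- off + 21L
  }
  names(out) <- feature_names(schemes)
  out
}

#' Canonical feature identifiers F1..F188
#'
#' The concatenation order is frozen: F1-F20 are the amino-acid composition
#' entries; then, per scheme in the order of [property_schemes()], 3
#' composition, 15 distribution and 3 transition entries.
#'
#' @param schemes list of property schemes (default the 8 built-ins)
#' @return character vector `c("F1", ..., "F188")`
#' @export
feature_names <- function(schemes = property_schemes()) {
  paste0("F", seq_len(20L + 21L * length(schemes)))
}

#' Human-readable descriptions of the 188 features
#'
#' @param schemes list of property schemes (default the 8 built-ins)
#' @return character vector parallel to [feature_names()] describing each
#'   entry (residue or scheme, descriptor family, class, percentile)
#' @export
feature_descriptions <- function(schemes = property_schemes()) {
  per_scheme <- function(nm) {
    c(paste0(nm, ".comp.c", 1:3),
      paste0(nm, ".dist.c", rep(1:3, each = 5), ".q",
             rep(c("first", "25", "50", "75", "100"), 3)),
      paste0(nm, ".trans.", c("c1c2", "c1c3", "c2c3")))
  }
  c(paste0("aac.", AA_ALPHABET),
    unlist(lapply(names(schemes), per_scheme), use.names = FALSE))
}

#' Encode a protein set into a feature matrix
#'
#' @param records a `protein_set`
#' @param schemes list of property schemes (default the 8 built-ins)
#' @return a `feature_matrix`: numeric matrix (rows = records, columns =
#'   F1..F188) with row names set to record ids and the labels stored in
#'   attribute `"labels"`
#' @export
encode_dataset <- function(records, schemes = property_schemes()) {
  stopifnot(inherits(records, "protein_set"))
  if (nrow(records) == 0L) stop_validation("no records to encode")
  if (anyDuplicated(records$id)) stop_validation("duplicate record ids")
  m <- t(vapply(records$sequence, encode_sequence,
                numeric(20L + 21L * length(schemes)), schemes = schemes,
                USE.NAMES = FALSE))
  rownames(m) <- records$id
  colnames(m) <- feature_names(schemes)
  attr(m, "labels") <- records$label
  class(m) <- c("feature_matrix", class(m))
  m
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d sequences x %d features\n", nrow(x), ncol(x)))
  lab <- attr(x, "labels")
  if (!is.null(lab)) {
    tb <- table(lab)
    cat("labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a feature matrix to a data frame
#'
#' @param x a `feature_matrix`
#' @param ... unused
#' @return data frame with columns `id`, `label`, `F1`..`F188`
#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  m <- unclass(x)
  lab <- attr(x, "labels") %||% rep("unlabeled", nrow(m))
  attr(m, "labels") <- NULL
  data.frame(id = rownames(m), label = lab, m,
             row.names = NULL, check.names = FALSE)
}

#' Write a feature matrix to CSV
#'
#' Header is `id,label,F1,...,F188`.
#'
#' @param x a `feature_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path a CSV written by [write_feature_csv()]
#' @return a `feature_matrix`
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop_validation("feature CSV must have 'id' and 'label' columns")
  m <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(m) <- df$id
  attr(m, "labels") <- df$label
  class(m) <- c("feature_matrix", class(m))
  m
}

#' Write a feature matrix to ARFF
#'
#' ARFF keeps the encoding interoperable with Weka-based workflows.
#'
#' @param x a `feature_matrix`
#' @param path output file path
#' @param relation ARFF relation name
#' @return `path`, invisibly
#' @export
write_feature_arff <- function(x, path, relation = "abctk_features") {
  df <- as.data.frame(x)
  df$id <- NULL
  df$label <- factor(df$label)
  df <- df[, c(setdiff(names(df), "label"), "label")]
  foreign::write.arff(df, path, relation = relation)
  invisible(path)
}

# sequence string -> integer residue indices (1..20)
seq_to_int <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_validation("sequence must be a single character string")
  idx <- match(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (anyNA(idx))
    stop_validation("sequence contains non-canonical residues; sanitize first")
  idx
}

# residue class indices (1..3) under one scheme
class_index <- function(sequence, scheme) {
  validate_scheme(scheme)
  lut <- integer(20L)
  for (i in 1:3) lut[match(scheme$classes[[i]], AA_ALPHABET)] <- i
  lut[seq_to_int(sequence)]
}
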