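#' Sanitize a raw protein sequence
#'
#' Normalizes a sequence into the 20-letter amino-acid alphabet the encoder
#' requires: upper-cases, strips whitespace, gap (`-`) and stop (`*`)
#' characters, then applies the ambiguity policy to letters outside the
#' canonical alphabet (B, Z, X, U, O, J and anything else non-standard).
#'
#' @param raw character scalar, the raw sequence
#' @param ambiguity how to treat non-canonical residues: `"drop-residue"`
#'   (default; remove the character, keep the sequence) or
#'   `"reject-sequence"` (discard the whole record)
#' @param min_length minimum accepted length after cleaning; default 2 because
#'   transition features divide by L - 1
#' @return a list with `ok` (logical), `sequence` (cleaned string if `ok`),
#'   and `reason` (character, why the sequence was rejected, if not)
#' @examples
#' sanitize_sequence("acd-k*")$sequence
#' sanitize_sequence("ACXDK")$sequence
#' sanitize_sequence("XXXX")$ok
#' @export
sanitize_sequence <- function(raw,
                              ambiguity = c("drop-residue", "reject-sequence"),
                              min_length = 2L) {
  ambiguity <- match.arg(ambiguity)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    return(list(ok = FALSE, sequence = NA_character_, reason = "empty input"))
  s <- toupper(gsub("[[:space:]*-]", "", raw))
  chars <- strsplit(s, "")[[1]]
  canonical <- chars %in% AA_ALPHABET
  if (!all(canonical)) {
    if (ambiguity == "reject-sequence")
      return(list(ok = FALSE, sequence = NA_character_,
                  reason = "non-canonical residue"))
    chars <- chars[canonical]
  }
  if (length(chars) < min_length)
    return(list(ok = FALSE, sequence = NA_character_,
                reason = sprintf("shorter than %d residues after cleaning",
                                 min_length)))
  list(ok = TRUE, sequence = paste(chars, collapse = ""), reason = NA_character_)
}

#' Build a validated protein set
#'
#' The package's record container: a data frame with columns `id`, `sequence`
#' and `label`, classed `"protein_set"`. Invariants enforced: unique non-empty
#' ids, sequences over the 20-letter alphabet, length >= 2.
#'
#' @param id character vector of unique identifiers
#' @param sequence character vector of sanitized sequences
#' @param label class labels: `"positive"`, `"negative"` or `"unlabeled"`
#' @return a `protein_set` data frame
#' @export
protein_set <- function(id, sequence, label = "unlabeled") {
  if (length(id) != length(sequence))
    stop_validation("id and sequence must have equal length")
  if (any(!nzchar(id))) stop_validation("empty id")
  if (anyDuplicated(id))
    stop_validation("duplicate ids: %s",
                    paste(unique(id[duplicated(id)]), collapse = ", "))
  label <- rep_len(as.character(label), length(id))
  bad_lab <- setdiff(unique(label), c("positive", "negative", "unlabeled"))
  if (length(bad_lab))
    stop_validation("unknown label(s): %s", paste(bad_lab, collapse = ", "))
  if (any(nchar(sequence) < 2L))
    stop_validation("sequences must have length >= 2")
  if (any(grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), sequence)))
    stop_validation("sequences contain non-canonical residues; sanitize first")
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' @export
print.protein_set <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("positive", "negative", "unlabeled")))
  cat(sprintf("protein_set: %d sequences (%d positive, %d negative, %d unlabeled)\n",
              nrow(x), tab[["positive"]], tab[["negative"]], tab[["unlabeled"]]))
  cat(sprintf("lengths: %d-%d (median %d)\n",
              min(nchar(x$sequence)), max(nchar(x$sequence)),
              as.integer(stats::median(nchar(x$sequence)))))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file, takes the text before the first
#' whitespace of each description line as the record id, sanitizes every
#' sequence with [sanitize_sequence()], and drops records that fail
#' sanitization, counting them in a rejection tally.
#'
#' @param path path to a FASTA file
#' @param label class label attached to every record (`"positive"`,
#'   `"negative"` or `"unlabeled"`)
#' @param ambiguity ambiguity policy passed to [sanitize_sequence()]
#' @return a `protein_set`; the number of rejected entries is attached as
#'   attribute `"rejected"` and a per-reason breakdown as `"rejection_reasons"`
#' @export
read_fasta <- function(path, label = "unlabeled",
                       ambiguity = c("drop-residue", "reject-sequence")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop_validation("FASTA file not found: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop_validation("no FASTA entries in %s", path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`, character(1), 1L)
  raw <- as.character(seqs)
  cleaned <- lapply(raw, sanitize_sequence, ambiguity = ambiguity)
  ok <- vapply(cleaned, `[[`, logical(1), "ok")
  reasons <- vapply(cleaned[!ok], `[[`, character(1), "reason")
  if (!any(ok)) stop_validation("no parseable entries in %s after sanitization", path)
  out <- protein_set(ids[ok],
                     vapply(cleaned[ok], `[[`, character(1), "sequence"),
                     label)
  attr(out, "rejected") <- sum(!ok)
  attr(out, "rejection_reasons") <- if (length(reasons)) table(reasons) else table(character())
  out
}

#' Write a protein set to FASTA
#'
#' @param records a `protein_set`
#' @param path output file path
#' @param width line width for the sequence lines
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(inherits(records, "protein_set"))
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Write a labels table alongside a FASTA export
#'
#' @param records a `protein_set`
#' @param path output TSV path (columns `id`, `label`)
#' @return `path`, invisibly
#' @export
write_labels <- function(records, path) {
  stopifnot(inherits(records, "protein_set"))
  utils::write.table(records[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
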