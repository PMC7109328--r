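#' Greedy sequence redundancy reduction
#'
#' Removes near-duplicate sequences above a pairwise identity threshold using
#' greedy incremental clustering in descending length order, the scheme
#' popularized by CD-HIT: each sequence becomes a new cluster representative
#' unless its identity to an existing (longer or equal) representative reaches
#' the threshold. The built-in identity measure is an approximation: candidate
#' pairs are screened for at least one shared k-mer (k = 3), and identity is
#' the maximal number of matching residues over all ungapped offsets, divided
#' by the length of the shorter sequence. For exact CD-HIT behaviour an
#' external `cd-hit` executable can be used instead.
#'
#' @param records a `protein_set`
#' @param threshold identity threshold in (0, 1]; default 0.6
#' @param method `"builtin"` (default) or `"cdhit"` (shells out to an
#'   installed CD-HIT binary with `-c threshold`)
#' @param cdhit_path path to the CD-HIT executable when `method = "cdhit"`
#' @param word_size k-mer size for the builtin screening filter
#' @return a `protein_set` containing the cluster representatives, in
#'   descending length order (ties keep input order); deterministic for a
#'   fixed input
#' @export
reduce_redundancy <- function(records, threshold = 0.6,
                              method = c("builtin", "cdhit"),
                              cdhit_path = "cd-hit", word_size = 3L) {
  stopifnot(inherits(records, "protein_set"))
  method <- match.arg(method)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_validation("threshold must be in (0, 1]")
  if (nrow(records) <= 1L) return(records)
  if (method == "cdhit") return(reduce_with_cdhit(records, threshold, cdhit_path))

  ord <- order(-nchar(records$sequence))
  seqs <- records$sequence[ord]
  reps <- integer(0)            # indices (into ord) of representatives
  rep_kmers <- list()
  for (i in seq_along(seqs)) {
    km <- seq_kmers(seqs[i], word_size)
    redundant <- FALSE
    for (j in seq_along(reps)) {
      if (!any(km %in% rep_kmers[[j]])) next
      if (ungapped_identity(seqs[reps[j]], seqs[i]) >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      reps <- c(reps, i)
      rep_kmers[[length(reps)]] <- km
    }
  }
  out <- records[ord[reps], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

# distinct k-mers of a sequence
seq_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(s)
  unique(substring(s, 1:(L - k + 1L), k:L))
}

# best ungapped-overlap identity: max matches over all offsets, normalized by
# the shorter length
ungapped_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) < length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  La <- length(ca); Lb <- length(cb)
  best <- 0L
  for (off in (-(Lb - 1L)):(La - 1L)) {
    ia <- max(1L, off + 1L)
    ib <- max(1L, 1L - off)
    len <- min(La - ia, Lb - ib) + 1L
    if (len <= best) next
    m <- sum(ca[ia:(ia + len - 1L)] == cb[ib:(ib + len - 1L)])
    if (m > best) best <- m
  }
  best / Lb
}

reduce_with_cdhit <- function(records, threshold, cdhit_path) {
  if (Sys.which(cdhit_path) == "" && !file.exists(cdhit_path))
    stop_validation("CD-HIT executable not found: %s", cdhit_path)
  tmp_in <- tempfile(fileext = ".fasta")
  tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out, paste0(tmp_out, ".clstr"))), add = TRUE)
  write_fasta(records, tmp_in)
  status <- system2(cdhit_path,
                    c("-i", tmp_in, "-o", tmp_out, "-c", format(threshold), "-n", "4"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tmp_out))
    stop_validation("CD-HIT run failed (exit status %d)", status)
  kept <- read_fasta(tmp_out)
  idx <- match(kept$id, records$id)
  out <- records[idx[!is.na(idx)], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Build a positive/negative sample pool
#'
#' @param positives a `protein_set` (labels forced to `"positive"`)
#' @param negatives a `protein_set` (labels forced to `"negative"`)
#' @return a `sample_pool` list with elements `positives` and `negatives`;
#'   ids must be unique across the two sets
#' @export
sample_pool <- function(positives, negatives) {
  stopifnot(inherits(positives, "protein_set"), inherits(negatives, "protein_set"))
  positives$label <- "positive"
  negatives$label <- "negative"
  if (anyDuplicated(c(positives$id, negatives$id)))
    stop_validation("ids must be unique across positives and negatives")
  structure(list(positives = positives, negatives = negatives),
            class = "sample_pool")
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("sample_pool: %d positives / %d negatives\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

#' Repeated balanced undersampling splits
#'
#' Balances an imbalanced pool by repeated random undersampling: in each of
#' `repeats` repetitions, as many negatives as there are positives are drawn
#' without replacement to join all positives in the training set, and the
#' remaining negatives form that repetition's held-out test set. Each
#' repetition draws with an independent sub-seed derived from `seed`, so a
#' fixed seed reproduces the splits exactly.
#'
#' Note the protocol's held-out sets contain only negatives, so hold-out
#' accuracy on them equals specificity on unseen negatives (see
#' [evaluate_holdout()]).
#'
#' @param pool a `sample_pool`
#' @param repeats number of repetitions (default 10)
#' @param seed master seed (integer)
#' @return a list of `repeats` `balanced_split` objects, each a list with
#'   `repetition`, `seed` (the derived sub-seed), `train` (a `protein_set` of
#'   all positives plus the sampled negatives) and `test` (a `protein_set` of
#'   the remaining negatives)
#' @export
make_balanced_splits <- function(pool, repeats = 10L, seed) {
  stopifnot(inherits(pool, "sample_pool"))
  if (missing(seed)) stop_validation("seed is required")
  n_pos <- nrow(pool$positives)
  n_neg <- nrow(pool$negatives)
  if (n_pos < 1L) stop_validation("need at least one positive sample")
  if (n_neg < n_pos)
    stop_validation("fewer negatives (%d) than positives (%d)", n_neg, n_pos)
  if (repeats < 1L) stop_validation("repeats must be >= 1")
  lapply(seq_len(repeats), function(r) {
    sub_seed <- derive_seed(seed, r)
    set.seed(sub_seed)
    take <- sort(sample.int(n_neg, n_pos))
    train <- rbind(pool$positives, pool$negatives[take, , drop = FALSE])
    test <- pool$negatives[-take, , drop = FALSE]
    rownames(train) <- rownames(test) <- NULL
    class(train) <- class(test) <- c("protein_set", "data.frame")
    structure(list(repetition = r, seed = sub_seed, train = train, test = test),
              class = "balanced_split")
  })
}

#' @export
print.balanced_split <- function(x, ...) {
  cat(sprintf("balanced_split %d (seed %d): train %d (%d+/%d-), test %d negatives\n",
              x$repetition, x$seed, nrow(x$train),
              sum(x$train$label == "positive"), sum(x$train$label == "negative"),
              nrow(x$test)))
  invisible(x)
}

#' Write split manifests and FASTA exports
#'
#' Writes one JSON manifest per split (repetition index, sub-seed, train and
#' test ids) and per-split train/test FASTA files.
#'
#' @param splits list of `balanced_split` objects
#' @param dir output directory (created if absent)
#' @return character vector of manifest paths, invisibly
#' @export
write_split_manifests <- function(splits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(splits, function(s) {
    stem <- file.path(dir, sprintf("split_%02d", s$repetition))
    manifest <- list(repetition = s$repetition, seed = s$seed,
                     train_ids = s$train$id, train_labels = s$train$label,
                     test_ids = s$test$id)
    jsonlite::write_json(manifest, paste0(stem, ".json"), auto_unbox = TRUE)
    write_fasta(s$train, paste0(stem, "_train.fasta"))
    if (nrow(s$test) > 0L) write_fasta(s$test, paste0(stem, "_test.fasta"))
    paste0(stem, ".json")
  }, character(1))
  invisible(paths)
}
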