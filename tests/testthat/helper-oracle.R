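# Independent brute-force oracle for the 188D encoder.
#
# Written deliberately with per-character loops and its own transcription of
# the eight physicochemical partitions, sharing no code with the package
# implementation.

ORACLE_AA <- "ACDEFGHIKLMNPQRSTVWY"

ORACLE_SCHEMES <- list(
  c("RKEDQN", "GASTPHY", "CVLIMFW"),       # hydrophobicity
  c("GASCTPD", "NVEQIL", "MHKFRYW"),       # normalized van der Waals volume
  c("LIFWCMVY", "PATGS", "HQRKNED"),       # polarity
  c("GASDT", "CPNVEQIL", "KMHFRYW"),       # polarizability
  c("KR", "ANCQGHILMFPSTWYV", "DE"),       # charge
  c("GQDNAHR", "KTSEC", "ILMFPWYV"),       # surface tension
  c("EALMQKRH", "VIYCWFT", "GNPSD"),       # secondary structure
  c("ALFCGIVW", "RKQEND", "MPSTHY")        # solvent accessibility
)

oracle_class_of <- function(ch, scheme) {
  for (i in 1:3) {
    cls <- scheme[i]
    for (j in seq_len(nchar(cls))) {
      if (substr(cls, j, j) == ch) return(i)
    }
  }
  stop("unknown residue ", ch)
}

oracle_encode <- function(s) {
  L <- nchar(s)
  out <- numeric(0)
  # amino-acid composition
  for (k in seq_len(nchar(ORACLE_AA))) {
    aa <- substr(ORACLE_AA, k, k)
    cnt <- 0
    for (p in seq_len(L)) if (substr(s, p, p) == aa) cnt <- cnt + 1
    out <- c(out, cnt / L)
  }
  for (scheme in ORACLE_SCHEMES) {
    # composition
    for (i in 1:3) {
      cnt <- 0
      for (p in seq_len(L))
        if (oracle_class_of(substr(s, p, p), scheme) == i) cnt <- cnt + 1
      out <- c(out, cnt / L)
    }
    # distribution
    for (i in 1:3) {
      occ <- c()
      for (p in seq_len(L))
        if (oracle_class_of(substr(s, p, p), scheme) == i) occ <- c(occ, p)
      m <- length(occ)
      if (m == 0) {
        out <- c(out, rep(0, 5))
      } else {
        out <- c(out, occ[1] / L)
        for (q in c(0.25, 0.5, 0.75, 1)) out <- c(out, occ[ceiling(q * m)] / L)
      }
    }
    # transitions
    n12 <- n13 <- n23 <- 0
    for (p in seq_len(L - 1)) {
      a <- oracle_class_of(substr(s, p, p), scheme)
      b <- oracle_class_of(substr(s, p + 1, p + 1), scheme)
      if ((a == 1 && b == 2) || (a == 2 && b == 1)) n12 <- n12 + 1
      if ((a == 1 && b == 3) || (a == 3 && b == 1)) n13 <- n13 + 1
      if ((a == 2 && b == 3) || (a == 3 && b == 2)) n23 <- n23 + 1
    }
    out <- c(out, n12 / (L - 1), n13 / (L - 1), n23 / (L - 1))
  }
  out
}

# uniform random sequence over the 20-letter alphabet
random_seq <- function(L) {
  paste(sample(strsplit(ORACLE_AA, "")[[1]], L, replace = TRUE),
        collapse = "")
}

# rank-based Mann-Whitney AUC estimate with midrank tie handling
mw_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small separable fixture shared by model and embedding tests
separable_features <- function(n_per_class, seed, delta = 0.3,
                               length_range = c(100, 400)) {
  pool <- generate_dataset(synthetic_spec(
    n_positive = n_per_class, n_negative = n_per_class,
    length_range = length_range, delta = delta, seed = seed))
  recs <- rbind(pool$positives, pool$negatives)
  class(recs) <- c("protein_set", "data.frame")
  encode_dataset(recs)
}

# minimal evaluation_report with a prescribed accuracy, for aggregation tests
cv_stub <- function(acc, n, family = "random_forest") {
  correct <- round(acc * n)
  tp <- ceiling(correct / 2)
  tn <- correct - tp
  wrong <- n - correct
  fp <- ceiling(wrong / 2)
  fn <- wrong - fp
  abctk:::new_evaluation_report(family, "split", compute_metrics(tp, tn, fp, fn))
}
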