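schemes <- property_schemes()

test_that("the eight built-in property schemes partition the alphabet", {
  expect_named(schemes, c("hydrophobicity", "normalized_vdw_volume",
                          "polarity", "polarizability", "charge",
                          "surface_tension", "secondary_structure",
                          "solvent_accessibility"))
  for (s in schemes) {
    expect_silent(validate_scheme(s))
    expect_equal(sort(unlist(s$classes)), sort(strsplit(ORACLE_AA, "")[[1]]))
  }
  expect_equal(schemes$charge$classes[[1]], c("K", "R"))
  expect_equal(schemes$charge$classes[[3]], c("D", "E"))
})

test_that("amino-acid composition matches hand counts and sums to one", {
  v <- amino_acid_composition("ACDK")
  expect_equal(v, c(0.25, 0.25, 0.25, 0, 0, 0, 0, 0, 0.25,
                    rep(0, 11)))
  expect_equal(amino_acid_composition("AAAA")[1], 1)
  set.seed(42)
  for (L in c(2, 7, 153)) {
    expect_equal(sum(amino_acid_composition(random_seq(L))), 1)
  }
})

test_that("class composition matches hand counts against the charge partition", {
  expect_equal(class_composition("ACDK", schemes$charge), c(1, 2, 1) / 4)
  expect_equal(class_composition("KRKR", schemes$charge), c(1, 0, 0))
  set.seed(1)
  for (s in schemes) expect_equal(sum(class_composition(random_seq(60), s)), 1)
})

test_that("class distribution follows the ceil-percentile rule over occurrences", {
  # KR occurrences of charge class 1 at every position of KRKR
  expect_equal(class_distribution("KRKR", schemes$charge)[1:5],
               c(0.25, 0.25, 0.50, 0.75, 1.00))
  # single occurrence: all five anchors collapse onto it
  expect_equal(class_distribution("ACDK", schemes$charge)[11:15],
               rep(0.75, 5))
  # absent class contributes zeros
  expect_equal(class_distribution("KRKR", schemes$charge)[11:15], rep(0, 5))
})

test_that("bivalent transitions count unordered between-class pairs over L-1", {
  expect_equal(class_transition("AD", schemes$charge), c(0, 0, 1))
  expect_equal(class_transition("AAAA", schemes$hydrophobicity), c(0, 0, 0))
  expect_equal(class_transition("ACDK", schemes$charge), c(0, 1 / 3, 1 / 3))
})

test_that("a homopolymer encodes to the closed-form vector", {
  v <- encode_sequence(strrep("A", 20))
  expect_equal(unname(v[1]), 1)            # F(A)
  expect_equal(unname(sum(v[2:20])), 0)
  for (k in seq_along(schemes)) {
    block <- v[(20 + (k - 1) * 21 + 1):(20 + k * 21)]
    i <- which(vapply(schemes[[k]]$classes, function(cl) "A" %in% cl, logical(1)))
    expect_equal(unname(block[1:3]), as.numeric(1:3 == i))
    expect_equal(unname(block[3 + (i - 1) * 5 + 1:5]),
                 c(0.05, 0.25, 0.50, 0.75, 1.00))
    expect_equal(unname(block[19:21]), c(0, 0, 0))  # no between-class pairs
  }
})

test_that("encode_sequence agrees with the brute-force oracle encoder", {
  set.seed(2024)
  for (i in 1:40) {
    s <- random_seq(sample(2:150, 1))
    expect_equal(unname(encode_sequence(s)), oracle_encode(s),
                 tolerance = 1e-13)
  }
})

test_that("feature-vector invariants hold on random sequences", {
  set.seed(7)
  for (i in 1:25) {
    v <- encode_sequence(random_seq(sample(2:400, 1)))
    expect_length(v, 188)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v[1:20]), 1, tolerance = 1e-9)
    for (k in 1:8) {
      off <- 20 + (k - 1) * 21
      expect_equal(sum(v[off + 1:3]), 1, tolerance = 1e-9)
      expect_lte(sum(v[off + 19:21]), 1 + 1e-12)
    }
  }
})

test_that("sequence reversal preserves all composition features exactly", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_seq(sample(5:200, 1))
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    vs <- encode_sequence(s)
    vr <- encode_sequence(r)
    comp_idx <- c(1:20, as.vector(sapply(1:8, function(k) 20 + (k - 1) * 21 + 1:3)))
    expect_identical(vs[comp_idx], vr[comp_idx])
  }
})

test_that("the feature-name order is frozen (golden file)", {
  golden <- read.delim(test_path("golden-feature-names.tsv"), header = FALSE)
  expect_identical(feature_names(), golden$V1)
  expect_identical(feature_descriptions(), golden$V2)
})

test_that("encode_dataset preserves order, labels and is permutation-equivariant", {
  set.seed(5)
  recs <- protein_set(paste0("p", 1:6),
                      vapply(rep(40, 6), random_seq, character(1)),
                      label = rep(c("positive", "negative"), 3))
  fm <- encode_dataset(recs)
  expect_equal(dim(fm), c(6L, 188L))
  expect_equal(rownames(fm), recs$id)
  expect_equal(attr(fm, "labels"), recs$label)
  perm <- c(4, 2, 6, 1, 3, 5)
  recs_p <- recs[perm, ]
  class(recs_p) <- c("protein_set", "data.frame")
  fm_p <- encode_dataset(recs_p)
  expect_equal(unclass(fm_p)[, ], unclass(fm)[perm, ], ignore_attr = TRUE)
  dup <- recs
  dup$id[2] <- dup$id[1]
  expect_error(encode_dataset(dup), "duplicate")
})

test_that("feature matrices round-trip through CSV and export valid ARFF", {
  set.seed(6)
  recs <- protein_set(paste0("p", 1:4),
                      vapply(rep(60, 4), random_seq, character(1)),
                      label = c("positive", "positive", "negative", "negative"))
  fm <- encode_dataset(recs)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, csv)
  header <- strsplit(readLines(csv, n = 1), ",")[[1]]
  expect_equal(header[1:3], c("id", "label", "F1"))
  back <- read_feature_csv(csv)
  expect_equal(unclass(back)[, ], unclass(fm)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "labels"), attr(fm, "labels"))
  arff <- withr::local_tempfile(fileext = ".arff")
  write_feature_arff(fm, arff)
  df <- foreign::read.arff(arff)
  expect_equal(nrow(df), 4)
  expect_equal(ncol(df), 189)  # 188 features + class
  expect_equal(as.character(df$label), attr(fm, "labels"))
})

test_that("custom schemes can be loaded from YAML and must partition the alphabet", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("charge: [KR, ANCQGHILMFPSTWYV, DE]", f)
  s <- read_schemes(f)
  expect_equal(s$charge$classes, schemes$charge$classes)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("broken: [KR, ANCQGHILMFPSTWY, DE]", bad)  # V missing
  expect_error(read_schemes(bad), "partition")
})
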