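test_that("redundancy reduction collapses duplicates and keeps dissimilar sequences", {
  recs <- protein_set(c("a", "b"), c("MKVACDEKLW", "MKVACDEKLW"))
  expect_equal(nrow(reduce_redundancy(recs)), 1L)
  # no shared 3-mers at all
  recs2 <- protein_set(c("a", "b"), c("AAAAAAAAAA", "WWWWWWWWWW"))
  expect_equal(nrow(reduce_redundancy(recs2)), 2L)
  single <- protein_set("only", "ACDKACDK")
  expect_identical(reduce_redundancy(single), single)
})

test_that("redundancy reduction respects the identity threshold", {
  # 10 residues, 7 identical at the aligned offset -> identity 0.7
  a <- "ACDEFGHIKL"
  b <- "ACDEFGHWWW"
  recs <- protein_set(c("a", "b"), c(a, b))
  expect_equal(nrow(reduce_redundancy(recs, threshold = 0.6)), 1L)
  expect_equal(nrow(reduce_redundancy(recs, threshold = 0.8)), 2L)
  expect_error(reduce_redundancy(recs, threshold = 0), "threshold")
  expect_error(reduce_redundancy(recs, threshold = 1.5), "threshold")
})

test_that("redundancy reduction finds identity across ungapped offsets", {
  core <- "MKVACDEKLWQR"
  shifted <- paste0("GGG", core)        # same residues, offset by 3
  recs <- protein_set(c("long", "short"), c(shifted, core))
  expect_equal(reduce_redundancy(recs, threshold = 0.9)$id, "long")
})

test_that("redundancy reduction never grows and is idempotent", {
  set.seed(31)
  recs <- protein_set(paste0("s", 1:30),
                      vapply(sample(20:60, 30, replace = TRUE), random_seq,
                             character(1)))
  once <- reduce_redundancy(recs)
  twice <- reduce_redundancy(once)
  expect_lte(nrow(once), nrow(recs))
  expect_identical(twice$id, once$id)
})

test_that("an absent CD-HIT binary is a configuration error", {
  recs <- protein_set(c("a", "b"), c("ACDKACDK", "MKVMKVMK"))
  expect_error(reduce_redundancy(recs, method = "cdhit",
                                 cdhit_path = "/no/such/cd-hit"),
               "not found")
})

test_that("balanced splits have the required structure and partition the negatives", {
  set.seed(21)
  pool <- generate_dataset(synthetic_spec(n_positive = 12, n_negative = 40,
                                          length_range = c(30, 60), seed = 4))
  splits <- make_balanced_splits(pool, repeats = 5, seed = 99)
  expect_length(splits, 5)
  for (s in splits) {
    expect_equal(sum(s$train$label == "positive"), 12)
    expect_equal(sum(s$train$label == "negative"), 12)
    expect_true(all(s$test$label == "negative"))
    # sampled and held-out negatives partition the pool
    neg_train <- s$train$id[s$train$label == "negative"]
    expect_length(intersect(neg_train, s$test$id), 0)
    expect_setequal(c(neg_train, s$test$id), pool$negatives$id)
  }
})

test_that("an equal-size pool yields an empty test set", {
  pool <- generate_dataset(synthetic_spec(n_positive = 3, n_negative = 3,
                                          length_range = c(20, 30), seed = 2))
  s <- make_balanced_splits(pool, repeats = 1, seed = 5)[[1]]
  expect_equal(nrow(s$train), 6)
  expect_equal(nrow(s$test), 0)
})

test_that("splits are reproducible for a fixed seed and differ across repetitions", {
  pool <- generate_dataset(synthetic_spec(n_positive = 10, n_negative = 50,
                                          length_range = c(20, 40), seed = 8))
  a <- make_balanced_splits(pool, repeats = 3, seed = 7)
  b <- make_balanced_splits(pool, repeats = 3, seed = 7)
  expect_identical(lapply(a, `[[`, "train"), lapply(b, `[[`, "train"))
  expect_identical(lapply(a, `[[`, "test"), lapply(b, `[[`, "test"))
  # independent sub-seeds: repetitions draw different negatives
  neg1 <- a[[1]]$train$id[a[[1]]$train$label == "negative"]
  neg2 <- a[[2]]$train$id[a[[2]]$train$label == "negative"]
  expect_false(identical(neg1, neg2))
  expect_false(identical(a[[1]]$seed, a[[2]]$seed))
})

test_that("split validation rejects impossible pools", {
  pool <- generate_dataset(synthetic_spec(n_positive = 10, n_negative = 50,
                                          length_range = c(20, 40), seed = 8))
  small <- sample_pool(pool$positives, pool$negatives[1:5, ])
  expect_error(make_balanced_splits(small, repeats = 2, seed = 1),
               "fewer negatives")
  expect_error(make_balanced_splits(pool, repeats = 0, seed = 1), "repeats")
  expect_error(make_balanced_splits(pool, repeats = 2), "seed")
})

test_that("split manifests record ids and seeds and are byte-stable", {
  pool <- generate_dataset(synthetic_spec(n_positive = 5, n_negative = 20,
                                          length_range = c(20, 40), seed = 3))
  splits <- make_balanced_splits(pool, repeats = 2, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_split_manifests(splits, d1)
  p2 <- write_split_manifests(splits, d2)
  m <- jsonlite::read_json(p1[1])
  expect_equal(m$repetition, 1)
  expect_equal(m$seed, splits[[1]]$seed)
  expect_length(m$train_ids, 10)
  expect_length(m$test_ids, 15)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_true(file.exists(file.path(d1, "split_01_train.fasta")))
})
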