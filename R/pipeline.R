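#' Default pipeline configuration
#'
#' Returns the fully-resolved default configuration for [run_pipeline()].
#' Every field can be overridden via a YAML file or an override list; every
#' random stage draws its own sub-seed from the single master `seed`.
#'
#' @param seed master seed
#' @param output_dir where artifacts are written
#' @return a nested list of configuration defaults
#' @export
default_config <- function(seed = 1L, output_dir = "abctk_run") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    input = list(positive_fasta = NULL, negative_fasta = NULL,
                 ambiguity = "drop-residue"),
    synthetic = list(n_positive = 875L, n_negative = 9736L,
                     length_range = c(100L, 400L), delta = 0.3,
                     biased_set = c("C", "V", "L", "I", "M", "F", "W"),
                     background = "uniform"),
    redundancy = list(method = "none", threshold = 0.6),
    split = list(repeats = 10L),
    train = list(classifiers = c("random_forest", "c45_tree", "naive_bayes",
                                 "svm", "knn"),
                 folds = 10L),
    tsne = list(enabled = TRUE, dims = 2L, perplexity = 10, theta = 0,
                max_iter = 1000L, exaggeration_factor = 8, max_points = 200L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file fall back to [default_config()].
#'
#' @param path YAML file path
#' @return resolved configuration list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full classification pipeline
#'
#' Executes, in order: sequence input (synthetic generation, or FASTA files
#' when configured), optional redundancy reduction, repeated balanced
#' undersampling splits, 188D encoding, per-split cross-validated training and
#' hold-out evaluation of every configured classifier with weighted
#' aggregation across splits, and a t-SNE embedding of the first training
#' set. Every artifact is written under `config$output_dir` and recorded in a
#' run manifest (JSON) with the seeds used, record counts and MD5 checksums,
#' so a rerun with the same configuration reproduces the manifest
#' byte-identically. Stage failures abort with the stage name and cause.
#'
#' @param config a configuration list ([default_config()] shape) or the path
#'   to a YAML file
#' @param verbose log stage progress to stderr
#' @return the manifest, invisibly (also written to
#'   `output_dir/manifest.json`)
#' @export
run_pipeline <- function(config = default_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[abctk %s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- config$seed

  # --- input ----------------------------------------------------------------
  pool <- stage("seq_io", {
    if (!is.null(config$input$positive_fasta)) {
      pos <- read_fasta(config$input$positive_fasta, "positive",
                        ambiguity = config$input$ambiguity)
      neg <- read_fasta(config$input$negative_fasta, "negative",
                        ambiguity = config$input$ambiguity)
      log_msg("seq_io", "read %d positives (%d rejected), %d negatives (%d rejected)",
              nrow(pos), attr(pos, "rejected"), nrow(neg), attr(neg, "rejected"))
      sample_pool(pos, neg)
    } else {
      sp <- do.call(synthetic_spec,
                    c(config$synthetic, list(seed = derive_seed(seed, 1L))))
      p <- generate_dataset(sp)
      log_msg("synthetic", "generated %d positives, %d negatives",
              nrow(p$positives), nrow(p$negatives))
      p
    }
  })

  # --- redundancy reduction --------------------------------------------------
  if (config$redundancy$method != "none") {
    pool <- stage("datasets", {
      p2 <- sample_pool(
        reduce_redundancy(pool$positives, config$redundancy$threshold,
                          method = config$redundancy$method),
        reduce_redundancy(pool$negatives, config$redundancy$threshold,
                          method = config$redundancy$method))
      log_msg("datasets", "redundancy reduction kept %d positives, %d negatives",
              nrow(p2$positives), nrow(p2$negatives))
      p2
    })
  }

  # --- splits ---------------------------------------------------------------
  splits <- stage("datasets", {
    s <- make_balanced_splits(pool, repeats = config$split$repeats,
                              seed = derive_seed(seed, 2L))
    write_split_manifests(s, file.path(config$output_dir, "splits"))
    log_msg("datasets", "%d balanced splits (train %d, test %d)",
            length(s), nrow(s[[1]]$train), nrow(s[[1]]$test))
    s
  })

  # --- encoding -------------------------------------------------------------
  all_records <- stage("features", {
    recs <- rbind(pool$positives, pool$negatives)
    class(recs) <- c("protein_set", "data.frame")
    recs
  })
  fm <- stage("features", {
    m <- encode_dataset(all_records)
    write_feature_csv(m, file.path(config$output_dir, "features.csv"))
    log_msg("features", "encoded %d sequences into %d features", nrow(m), ncol(m))
    m
  })

  # --- training / evaluation ------------------------------------------------
  reports_dir <- file.path(config$output_dir, "reports")
  dir.create(reports_dir, showWarnings = FALSE)
  eval_summary <- list()
  stage("models", for (family in config$train$classifiers) {
    split_reports <- list()
    holdout_acc <- numeric(0)
    for (s in splits) {
      train_x <- fm[match(s$train$id, rownames(fm)), , drop = FALSE]
      spec <- classifier_spec(family, seed = derive_seed(seed, 100L + s$repetition))
      rep_cv <- cross_validate(train_x, spec,
                               folds = config$train$folds,
                               seed = derive_seed(seed, 200L + s$repetition),
                               labels = s$train$label)
      split_reports[[s$repetition]] <- rep_cv
      write_report_json(rep_cv, file.path(reports_dir,
        sprintf("%s_split%02d_cv.json", family, s$repetition)))
      if (nrow(s$test) > 0L) {
        model <- fit_classifier(train_x, s$train$label, spec)
        test_x <- fm[match(s$test$id, rownames(fm)), , drop = FALSE]
        rep_ho <- evaluate_holdout(model, test_x, labels = s$test$label)
        holdout_acc <- c(holdout_acc, rep_ho$acc)
        write_report_json(rep_ho, file.path(reports_dir,
          sprintf("%s_split%02d_holdout.json", family, s$repetition)))
      }
    }
    agg <- aggregate_reports(split_reports)
    write_report_json(agg, file.path(reports_dir,
                                     sprintf("%s_overall.json", family)))
    eval_summary[[family]] <- list(
      cv_acc = agg$acc, cv_sn = agg$sn, cv_sp = agg$sp, cv_mcc = agg$mcc,
      cv_auc = agg$auc,
      holdout_acc = if (length(holdout_acc)) mean(holdout_acc) else NULL)
    log_msg("models", "%s: CV ACC %.4f AUC %.4f%s", family, agg$acc, agg$auc,
            if (length(holdout_acc))
              sprintf(", hold-out ACC %.4f", mean(holdout_acc)) else "")
  })

  # --- embedding ------------------------------------------------------------
  embedding_file <- NULL
  if (isTRUE(config$tsne$enabled)) {
    stage("embedding", {
      train1 <- splits[[1]]$train
      idx <- match(train1$id, rownames(fm))
      if (length(idx) > config$tsne$max_points) {
        set.seed(derive_seed(seed, 3L))
        keep_pos <- sample(which(train1$label == "positive"),
                           ceiling(config$tsne$max_points / 2))
        keep_neg <- sample(which(train1$label == "negative"),
                           floor(config$tsne$max_points / 2))
        sel <- sort(c(keep_pos, keep_neg))
      } else sel <- seq_along(idx)
      sub <- fm[idx[sel], , drop = FALSE]
      attr(sub, "labels") <- train1$label[sel]
      class(sub) <- c("feature_matrix", class(sub))
      emb <- tsne_embed(sub, dims = config$tsne$dims,
                        perplexity = config$tsne$perplexity,
                        theta = config$tsne$theta,
                        max_iter = config$tsne$max_iter,
                        exaggeration_factor = config$tsne$exaggeration_factor,
                        seed = derive_seed(seed, 4L))
      embedding_file <- file.path(config$output_dir, "embedding.tsv")
      write_embedding_tsv(emb, embedding_file)
      log_msg("embedding", "embedded %d points; KL %.4f, silhouette %.3f",
              nrow(emb$coordinates), emb$kl_divergence,
              embedding_silhouette(emb))
    })
  }

  # --- manifest -------------------------------------------------------------
  out_files <- sort(setdiff(
    list.files(config$output_dir, recursive = TRUE),
    "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(config$output_dir, out_files)))
  names(checksums) <- out_files
  manifest <- list(
    package = "abctk",
    version = as.character(utils::packageVersion("abctk")),
    config = config,
    counts = list(positives = nrow(pool$positives),
                  negatives = nrow(pool$negatives),
                  splits = length(splits),
                  train_size = nrow(splits[[1]]$train),
                  test_size = nrow(splits[[1]]$test),
                  features = ncol(fm)),
    evaluation = eval_summary,
    artifacts = checksums)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline", "manifest written to %s",
          file.path(config$output_dir, "manifest.json"))
  invisible(manifest)
}
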