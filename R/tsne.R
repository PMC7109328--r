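#' Exact t-SNE embedding of a feature matrix
#'
#' Projects a feature matrix to `dims` dimensions with t-distributed
#' stochastic neighbor embedding, computed exactly (no Barnes-Hut
#' approximation; the `theta` argument is accepted for interface parity but
#' only `theta = 0` is supported). Input similarities are Gaussian conditional
#' probabilities calibrated by binary search to the target perplexity and
#' symmetrized; the embedding minimizes the Kullback-Leibler divergence from
#' the input similarities to a Student-t (df = 1) kernel in the embedding, by
#' gradient descent with momentum, adaptive per-coordinate gains and an early
#' exaggeration phase in which the input similarities are multiplied by
#' `exaggeration_factor` for the first `stop_lying_iter` iterations.
#'
#' @param x a `feature_matrix` or numeric matrix (rows = samples)
#' @param dims output dimensionality (default 2)
#' @param perplexity Gaussian-neighborhood perplexity (default 10); requires
#'   at least `3 * perplexity + 1` samples
#' @param theta Barnes-Hut accuracy parameter; must be 0 (exact)
#' @param max_iter gradient-descent iterations (default 1000)
#' @param exaggeration_factor early-exaggeration multiplier (default 8)
#' @param seed integer seed for the random initialization (default 42)
#' @param standardize center/scale columns before embedding (default FALSE;
#'   the 188D features already live in \[0, 1\])
#' @param eta learning rate (default 200)
#' @param stop_lying_iter iteration at which early exaggeration ends and
#'   momentum switches from 0.5 to 0.8 (default 250)
#' @param verbose print progress every 100 iterations
#' @return a `tsne_embedding`: list with `coordinates` (n x dims matrix, row
#'   names = input ids), `labels`, `kl_divergence` (final, on the
#'   un-exaggerated similarities) and `settings` (all arguments echoed)
#' @export
tsne_embed <- function(x, dims = 2L, perplexity = 10, theta = 0,
                       max_iter = 1000L, exaggeration_factor = 8,
                       seed = 42L, standardize = FALSE, eta = 200,
                       stop_lying_iter = 250L, verbose = FALSE) {
  if (theta != 0)
    stop_validation("only exact t-SNE is implemented; theta must be 0")
  ids <- rownames(x)
  labels <- attr(x, "labels")
  x <- strip_fm(x)
  n <- nrow(x)
  min_n <- 3 * perplexity + 1
  if (n < min_n)
    stop_validation("perplexity %g requires at least %d samples (got %d)",
                    perplexity, ceiling(min_n), n)
  if (standardize) {
    keep <- apply(x, 2, stats::sd) > 0
    x <- scale(x[, keep, drop = FALSE])
  }

  P <- input_similarities(x, perplexity)
  P <- pmax(P, .Machine$double.xmin)

  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  inc <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  for (iter in seq_len(max_iter)) {
    lying <- iter <= stop_lying_iter
    Pcur <- if (lying) P * exaggeration_factor else P
    momentum <- if (iter <= stop_lying_iter) 0.5 else 0.8

    num <- 1 / (1 + sq_dist(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, .Machine$double.xmin)

    Lmat <- (Pcur - Q) * num
    grad <- 4 * (diag(rowSums(Lmat)) - Lmat) %*% Y

    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (verbose && iter %% 100 == 0)
      message(sprintf("t-SNE iteration %d: KL = %.4f", iter,
                      sum(P * log(P / Q))))
  }
  num <- 1 / (1 + sq_dist(Y))
  diag(num) <- 0
  Q <- pmax(num / sum(num), .Machine$double.xmin)
  kl <- sum(P * log(P / Q))

  rownames(Y) <- ids
  structure(list(coordinates = Y, labels = labels, kl_divergence = kl,
                 settings = list(dims = dims, perplexity = perplexity,
                                 theta = theta, max_iter = max_iter,
                                 exaggeration_factor = exaggeration_factor,
                                 seed = seed, standardize = standardize,
                                 eta = eta, stop_lying_iter = stop_lying_iter)),
            class = "tsne_embedding")
}

# symmetrized perplexity-calibrated similarities
input_similarities <- function(x, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(x)
  D <- sq_dist(x)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    for (t in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sum_p) + beta * sum(di * p) / sum_p
        p <- p / sum_p
      }
      if (abs(H - target) < tol) break
      if (H > target) { beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else { beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P
}

# pairwise squared Euclidean distances
sq_dist <- function(m) {
  s <- rowSums(m^2)
  d <- outer(s, s, "+") - 2 * tcrossprod(m)
  d[d < 0] <- 0
  d
}

#' @export
print.tsne_embedding <- function(x, ...) {
  s <- x$settings
  cat(sprintf("tsne_embedding: %d points in %d-D (perplexity %g, %d iterations, exaggeration %g, seed %d)\n",
              nrow(x$coordinates), s$dims, s$perplexity, s$max_iter,
              s$exaggeration_factor, s$seed))
  cat(sprintf("final KL divergence: %.4f\n", x$kl_divergence))
  invisible(x)
}

#' Plot a t-SNE embedding colored by class label
#'
#' @param x a `tsne_embedding`
#' @param ... passed to [graphics::plot()]
#' @export
plot.tsne_embedding <- function(x, ...) {
  lab <- factor(x$labels %||% rep("unlabeled", nrow(x$coordinates)))
  graphics::plot(x$coordinates, col = as.integer(lab), pch = 19, cex = 0.6,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  graphics::legend("topright", legend = levels(lab),
                   col = seq_len(nlevels(lab)), pch = 19, bty = "n")
  invisible(x)
}

#' Write embedding coordinates to TSV (with a JSON settings sidecar)
#'
#' @param embedding a `tsne_embedding`
#' @param path output TSV path (columns `id`, `label`, `x`, `y`, ...); the
#'   settings and final KL divergence are written to `<path>.json`
#' @return `path`, invisibly
#' @export
write_embedding_tsv <- function(embedding, path) {
  stopifnot(inherits(embedding, "tsne_embedding"))
  co <- embedding$coordinates
  df <- data.frame(id = rownames(co) %||% seq_len(nrow(co)),
                   label = embedding$labels %||% "unlabeled", co)
  names(df)[-(1:2)] <- c("x", "y", paste0("dim", seq_len(ncol(co))))[seq_len(ncol(co))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(embedding$settings,
                         list(kl_divergence = embedding$kl_divergence)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean silhouette of an embedding against class labels
#'
#' @param embedding a `tsne_embedding` (or any list with `coordinates` and
#'   `labels`)
#' @return mean silhouette width in \[-1, 1\]
#' @export
embedding_silhouette <- function(embedding) {
  lab <- as.integer(factor(embedding$labels))
  if (length(unique(lab)) < 2L)
    stop_validation("silhouette requires at least two label groups")
  mean(cluster::silhouette(lab, stats::dist(embedding$coordinates))[, 3])
}

#' k-nearest-neighbor label purity of an embedding
#'
#' Fraction, averaged over points, of each point's k nearest embedding
#' neighbors sharing its label. Near 1 for well-separated classes; for
#' random labels, near the expected same-label fraction.
#'
#' @param embedding a `tsne_embedding`
#' @param k neighborhood size (default 10)
#' @param labels optional label override (e.g. a permutation, for null
#'   comparisons)
#' @return mean purity in \[0, 1\]
#' @export
neighbor_purity <- function(embedding, k = 10L, labels = NULL) {
  lab <- labels %||% embedding$labels
  co <- embedding$coordinates
  n <- nrow(co)
  if (k >= n) stop_validation("k must be below the number of points")
  D <- as.matrix(stats::dist(co))
  diag(D) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(lab[nb] == lab[i])
  }, numeric(1)))
}
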