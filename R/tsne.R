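#' Two-dimensional t-SNE embedding
#'
#' Exact (non-approximated) t-distributed stochastic neighbor embedding of a
#' samples x features matrix, used to furnish the two embedding coordinates
#' the tissue-of-origin classifier consumes. Perplexity is calibrated per
#' point by binary search; optimization uses early exaggeration (12x for the
#' first 250 iterations) and the standard momentum schedule. Seeded via R's
#' RNG, so the embedding is reproducible.
#'
#' @param x Numeric matrix (samples x features), no missing values.
#' @param perplexity Target perplexity (default 30); clamped to
#'   `(n - 1) / 3` with a warning for small n.
#' @param n_iter Gradient-descent iterations (default 1000).
#' @param eta Learning rate (default 200).
#' @param seed Integer seed.
#' @return n x 2 matrix of embedding coordinates (columns `tsne1`, `tsne2`).
#' @export
run_tsne <- function(x, perplexity = 30, n_iter = 1000L, eta = 200,
                     seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need >= 4 samples for a t-SNE embedding", call. = FALSE)
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  pmax_allowed <- (n - 1) / 3
  if (perplexity > pmax_allowed) {
    warning(sprintf("perplexity %.0f too large for n=%d; clamped to %.1f",
                    perplexity, n, pmax_allowed), call. = FALSE)
    perplexity <- pmax_allowed
  }
  d2 <- as.matrix(dist(x))^2
  y <- with_seed(seed, .tsne_exact(d2, perplexity, as.integer(n_iter), eta))
  colnames(y) <- c("tsne1", "tsne2")
  rownames(y) <- rownames(x)
  y
}
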