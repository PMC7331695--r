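#' Concordance between one CTC sample and its matched tumor
#'
#' Given aligned ternary call vectors (and optionally continuous values),
#' computes the directional detection statistics reported for tumor/CTC
#' pairs: sensitivity (tumor-altered features detected in the CTC with the
#' same sign), specificity (tumor-neutral features neutral in the CTC), a
#' strict shared-alteration fraction (same-sign agreement over the union of
#' features altered in either sample), and Pearson/Spearman correlations of
#' the continuous values. Ratios with a zero denominator are `NA`, never 0.
#' Features missing in either sample are dropped pairwise.
#'
#' @param ctc_calls,tumor_calls Named ternary vectors in \{-1, 0, 1\} over the
#'   same feature set.
#' @param ctc_values,tumor_values Optional continuous values (same features)
#'   for the correlations.
#' @param pair_id Identifier copied into the report.
#' @return A one-row data frame of class `concordance_report` with columns
#'   `pair_id`, `sensitivity`, `specificity`, `shared_fraction`, `pearson_r`,
#'   `spearman_rho`, `n_tumor_altered`, `n_tumor_neutral`.
#' @export
pair_concordance <- function(ctc_calls, tumor_calls, ctc_values = NULL,
                             tumor_values = NULL, pair_id = "pair") {
  if (length(ctc_calls) != length(tumor_calls) ||
      (!is.null(names(ctc_calls)) && !is.null(names(tumor_calls)) &&
       !identical(names(ctc_calls), names(tumor_calls)))) {
    stop("feature sets of the two samples do not align", call. = FALSE)
  }
  ok <- !is.na(ctc_calls) & !is.na(tumor_calls)
  ctc <- ctc_calls[ok]
  tum <- tumor_calls[ok]

  n_alt <- sum(tum != 0)
  n_neu <- sum(tum == 0)
  sens <- if (n_alt > 0) sum(tum != 0 & ctc == tum) / n_alt else NA_real_
  spec <- if (n_neu > 0) sum(tum == 0 & ctc == 0) / n_neu else NA_real_
  union_alt <- tum != 0 | ctc != 0
  shared <- if (any(union_alt)) {
    sum(ctc[union_alt] == tum[union_alt]) / sum(union_alt)
  } else NA_real_

  pear <- spear <- NA_real_
  if (!is.null(ctc_values) && !is.null(tumor_values)) {
    okv <- !is.na(ctc_values) & !is.na(tumor_values)
    if (sum(okv) >= 3 && sd(ctc_values[okv]) > 0 && sd(tumor_values[okv]) > 0) {
      pear <- cor(ctc_values[okv], tumor_values[okv], method = "pearson")
      spear <- cor(ctc_values[okv], tumor_values[okv], method = "spearman")
    }
  }

  out <- data.frame(
    pair_id = pair_id, sensitivity = sens, specificity = spec,
    shared_fraction = shared, pearson_r = pear, spearman_rho = spear,
    n_tumor_altered = n_alt, n_tumor_neutral = n_neu,
    stringsAsFactors = FALSE
  )
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' Sample-by-sample correlation matrix of SCNA values
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param method "pearson" or "spearman".
#' @return Symmetric correlation matrix with unit diagonal; samples with a
#'   constant value vector get `NA` off-diagonals with a warning. Missing
#'   features are handled pairwise-complete.
#' @export
correlation_matrix <- function(values, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need >= 2 samples", call. = FALSE)
  if (ncol(values) < 3) stop("need >= 3 features", call. = FALSE)
  const <- apply(values, 1, function(r) sd(r, na.rm = TRUE) == 0)
  if (any(const, na.rm = TRUE)) {
    warning("constant sample vector(s): ",
            paste(rownames(values)[which(const)], collapse = ", "),
            call. = FALSE)
  }
  m <- suppressWarnings(cor(t(values), method = method,
                            use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}

#' Unsupervised clustering of SCNA profiles with pair co-membership
#'
#' Agglomerative clustering with complete linkage on Euclidean distances,
#' the standard recipe for tumor/CTC SCNA heatmaps. For each labeled
#' CTC-tumor pair the report records whether the two samples merge with each
#' other before either merges with any other sample (i.e. the dendrogram
#' joins them as mutual first neighbours).
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids).
#' @param pairs Optional data frame with columns `ctc` and `tumor` naming
#'   paired rows of `values`.
#' @return List of class `scna_clustering` with `hclust`, `newick` (string)
#'   and, when `pairs` is given, a data frame `co_membership` with a logical
#'   `co_clustered` per pair.
#' @export
cluster_samples <- function(values, pairs = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  hc <- hclust(dist(values, method = "euclidean"), method = "complete")
  newick <- ape::write.tree(ape::as.phylo(hc))

  co <- NULL
  if (!is.null(pairs)) {
    stopifnot(all(c("ctc", "tumor") %in% names(pairs)))
    ids <- rownames(values)
    co_clustered <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      a <- match(pairs$ctc[k], ids)
      b <- match(pairs$tumor[k], ids)
      if (is.na(a) || is.na(b)) {
        stop(sprintf("pair %d names samples absent from `values`", k),
             call. = FALSE)
      }
      # co-clustered iff some merge joins exactly these two leaves
      co_clustered[k] <- any(
        (hc$merge[, 1] == -a & hc$merge[, 2] == -b) |
        (hc$merge[, 1] == -b & hc$merge[, 2] == -a)
      )
    }
    co <- cbind(pairs, co_clustered = co_clustered)
  }

  structure(list(hclust = hc, newick = newick, co_membership = co),
            class = "scna_clustering")
}

#' @export
print.scna_clustering <- function(x, ...) {
  cat(sprintf("scna_clustering: %d samples, complete linkage / Euclidean\n",
              length(x$hclust$labels)))
  if (!is.null(x$co_membership)) {
    cat(sprintf("pairs co-clustered: %d / %d\n",
                sum(x$co_membership$co_clustered), nrow(x$co_membership)))
  }
  invisible(x)
}
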