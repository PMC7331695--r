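#' Construct an SCNA matrix (samples x features)
#'
#' Container for continuous SCNA values (log2-ratio-like, 0 = neutral) and
#' ternary calls at the gene or cytoband level. Features are kept in genomic
#' order when intervals are available.
#'
#' @param values Numeric matrix, samples in rows, features in columns (column
#'   names are feature names).
#' @param level "gene" or "cytoband".
#' @param features Optional data frame `name`, `chrom`, `start`, `end` giving
#'   feature intervals; reordered to genomic position when present.
#' @param labels Optional per-sample class labels.
#' @param calls Optional ternary call matrix in \{-1, 0, 1\}.
#' @param tau Threshold used to derive `calls`, if any.
#' @return An object of class `scna_matrix`.
#' @export
scna_matrix <- function(values, level = c("cytoband", "gene"), features = NULL,
                        labels = NULL, calls = NULL, tau = NA_real_) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("`values` needs column names", call. = FALSE)
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature names", call. = FALSE)
  }
  if (!is.null(features)) {
    stopifnot(all(c("name", "chrom", "start", "end") %in% names(features)))
    features <- features[match(colnames(values), features$name), , drop = FALSE]
    ord <- order(features$chrom, features$start)
    features <- features[ord, , drop = FALSE]
    values <- values[, ord, drop = FALSE]
    if (!is.null(calls)) calls <- calls[, ord, drop = FALSE]
    rownames(features) <- NULL
  }
  if (!is.null(labels) && length(labels) != nrow(values)) {
    stop("`labels` length must equal the sample count", call. = FALSE)
  }
  structure(list(values = values, calls = calls, level = level,
                 features = features, labels = labels, tau = tau),
            class = "scna_matrix")
}

#' @export
print.scna_matrix <- function(x, ...) {
  cat(sprintf("scna_matrix: %d sample(s) x %d %s feature(s)%s%s\n",
              nrow(x$values), ncol(x$values), x$level,
              if (!is.null(x$calls)) sprintf(", calls at tau=%.3g", x$tau) else "",
              if (!is.null(x$labels)) sprintf(", %d classes",
                                              length(unique(x$labels))) else ""))
  invisible(x)
}

#' Collapse a bin-level profile to gene-level SCNA values
#'
#' Each gene receives the overlap-length-weighted mean of the log2 segment
#' ratio of the bins it intersects (strand is ignored: copy number is
#' strandless). Genes overlapping no bin are `NA`.
#'
#' @param profile A `cn_profile`.
#' @param genes Data frame with `chrom`, `start`, `end`, `name` (0-based
#'   half-open intervals).
#' @param eps Offset inside the log2 (matches segmentation).
#' @param cap Symmetric clamp for the log2 values (default 3): homozygous
#'   deletions would otherwise map to `log2(eps)` ~ -10 and dominate any
#'   downstream distance or correlation.
#' @return Named numeric vector of gene values (log2 scale, 0 = copy-neutral
#'   baseline; see Details).
#' @details Values are `log2(segment mean ratio * ploidy / baseline)` where
#'   the baseline is the sample's modal integer copy state — the state
#'   covering most of its genome — so that copy-neutral regions map to ~0
#'   and values are comparable across samples of different ploidy. (Rounding
#'   the fitted ploidy would misassign the baseline whenever the genome-wide
#'   mean state sits near a half-integer.)
#' @export
bins_to_genes <- function(profile, genes, eps = 1e-3, cap = 3) {
  if (is.null(genes) || nrow(genes) == 0) {
    stop("`genes` must contain at least one interval", call. = FALSE)
  }
  bins <- profile$bins
  # per-bin log2 value relative to the sample baseline
  bin_ratio <- rep(NA_real_, nrow(bins))
  for (k in seq_len(nrow(profile$segments))) {
    bin_ratio[profile$segments$start_bin[k]:profile$segments$end_bin[k]] <-
      profile$segments$mean_ratio[k]
  }
  states <- pmax(0, round(bin_ratio * profile$ploidy))
  tab <- table(states[!is.na(states) & states > 0])
  baseline <- if (length(tab) > 0) as.integer(names(tab)[which.max(tab)])
              else max(1, round(profile$ploidy))
  binval <- log2(pmax(bin_ratio * profile$ploidy, 0) / baseline + eps)
  binval <- pmin(pmax(binval, -cap), cap)

  out <- rep(NA_real_, nrow(genes))
  for (g in seq_len(nrow(genes))) {
    on_chrom <- which(bins$chrom == genes$chrom[g])
    if (length(on_chrom) == 0) next
    ov <- overlap_len(bins$start[on_chrom], bins$end[on_chrom],
                      genes$start[g], genes$end[g])
    hit <- ov > 0 & !is.na(binval[on_chrom])
    if (!any(hit)) next
    idx <- on_chrom[hit]
    out[g] <- sum(binval[idx] * ov[hit]) / sum(ov[hit])
  }
  names(out) <- genes$name
  out
}

#' Aggregate gene-level values to cytobands
#'
#' A cytoband's value is the unweighted mean of its member genes' values;
#' a gene belongs to the cytoband containing its midpoint (so a gene spanning
#' a band boundary is counted once). Cytobands with no genes are `NA`.
#'
#' @param gene_values Named numeric vector of gene values.
#' @param genes Data frame `chrom`, `start`, `end`, `name` matching
#'   `gene_values` names.
#' @param cytobands Data frame `chrom`, `start`, `end`, `name`.
#' @return Named numeric vector, one value per cytoband.
#' @export
genes_to_cytobands <- function(gene_values, genes, cytobands) {
  if (is.null(cytobands) || nrow(cytobands) == 0) {
    stop("`cytobands` must contain at least one interval", call. = FALSE)
  }
  genes <- genes[match(names(gene_values), genes$name), , drop = FALSE]
  mid <- (genes$start + genes$end) / 2
  out <- rep(NA_real_, nrow(cytobands))
  for (b in seq_len(nrow(cytobands))) {
    member <- genes$chrom == cytobands$chrom[b] &
      mid >= cytobands$start[b] & mid < cytobands$end[b]
    v <- gene_values[member]
    v <- v[!is.na(v)]
    if (length(v) > 0) out[b] <- mean(v)
  }
  names(out) <- cytobands$name
  out
}

#' Threshold continuous SCNA values into ternary calls
#'
#' `+1` where `value > tau`, `-1` where `value < -tau`, `0` otherwise
#' (strict inequalities: a value exactly at the threshold is neutral).
#' Missing values stay missing.
#'
#' @param values Numeric vector or matrix of SCNA values (log2 scale).
#' @param tau Positive call threshold (default 0.3, a GISTIC-like low-level
#'   cut).
#' @return Object of the same shape with entries in \{-1, 0, 1\} (and `NA`).
#' @export
call_ternary <- function(values, tau = 0.3) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("`tau` must be a single positive number", call. = FALSE)
  }
  out <- sign(values)
  out[!is.na(values) & abs(values) <= tau] <- 0
  out
}

#' Add ternary calls to an scna_matrix
#'
#' @param x An `scna_matrix`.
#' @param tau Call threshold, see [call_ternary()].
#' @return The matrix with its `calls` slot filled and `tau` recorded.
#' @export
add_calls <- function(x, tau = 0.3) {
  stopifnot(inherits(x, "scna_matrix"))
  x$calls <- call_ternary(x$values, tau)
  x$tau <- tau
  x
}

#' Restrict an SCNA matrix to a focus panel of loci
#'
#' Subsets the matrix to a named list of loci (cytobands or genes), in panel
#' order. Panel entries absent from the matrix are dropped with a warning
#' listing them; if none are present, a degenerate-input error is raised.
#'
#' @param x An `scna_matrix`.
#' @param panel Character vector of locus names, or a data frame whose first
#'   column holds them (the shape of the shipped 59-locus panel file).
#' @return An `scna_matrix` restricted to the panel columns.
#' @export
panel_extract <- function(x, panel) {
  stopifnot(inherits(x, "scna_matrix"))
  if (is.data.frame(panel)) panel <- as.character(panel[[1]])
  known <- panel %in% colnames(x$values)
  if (!any(known)) {
    stop("degenerate input: no panel locus present in the matrix", call. = FALSE)
  }
  if (any(!known)) {
    warning("panel loci absent from the matrix: ",
            paste(panel[!known], collapse = ", "), call. = FALSE)
  }
  keep <- panel[known]
  out <- x
  out$values <- x$values[, keep, drop = FALSE]
  if (!is.null(x$calls)) out$calls <- x$calls[, keep, drop = FALSE]
  if (!is.null(x$features)) {
    out$features <- x$features[match(keep, x$features$name), , drop = FALSE]
  }
  out
}
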