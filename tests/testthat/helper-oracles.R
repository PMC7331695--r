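# Independent oracles and small fixtures shared across the suite. The
# oracles deliberately use brute-force formulations so they stay independent
# of the code paths they check.

# Exhaustive least-squares segmentation into exactly k segments (dynamic
# programming over all split points); returns the sorted segment start
# indices.
dp_segment <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  sse <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, n, k)
  B <- matrix(0L, n, k)
  for (j in 1:n) D[j, 1] <- sse(1, j)
  if (k > 1) {
    for (t in 2:k) for (j in t:n) for (i in t:j) {
      v <- D[i - 1, t - 1] + sse(i, j)
      if (v < D[j, t]) { D[j, t] <- v; B[j, t] <- i }
    }
  }
  starts <- integer(k)
  j <- n
  if (k > 1) for (t in k:2) { starts[t] <- B[j, t]; j <- B[j, t] - 1L }
  starts[1] <- 1L
  starts
}

# Textbook Pearson correlation.
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Brute-force per-base gene value: average the bin-level value of every base
# the gene covers. Feasible only on small genomes.
gene_value_oracle <- function(bins, binval, gene) {
  vals <- rep(NA_real_, gene$end - gene$start)
  pos <- gene$start:(gene$end - 1)
  for (b in which(bins$chrom == gene$chrom)) {
    hit <- pos >= bins$start[b] & pos < bins$end[b]
    vals[hit] <- binval[b]
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Brute-force pairwise Euclidean distances.
euclid_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  }
  d
}

# A profile object with prescribed segments, for call-level tests that need
# exact bin values without running the read-level machinery.
fake_profile <- function(bins, segments, ploidy = 2, sample_id = "fake") {
  structure(list(sample_id = sample_id, bins = bins, segments = segments,
                 ploidy = ploidy,
                 raw_counts = rep(0L, nrow(bins)),
                 normalized_ratio = rep(1, nrow(bins)),
                 corrected_ratio = rep(1, nrow(bins)),
                 integer_states = rep(2L, nrow(bins))),
            class = "cn_profile")
}

# Shared small genome used by several suites (cheap to build, cached).
test_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_genome(4, 2e7, 250e3, genes_per_chrom = 40,
                                      bands_per_chrom = 6, seed = 11)
    g
  }
})

# Larger genome matching the study-scale conditions of the acceptance runs.
study_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_genome(6, 5e7, 250e3, genes_per_chrom = 80,
                                      bands_per_chrom = 8, seed = 1)
    g
  }
})
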