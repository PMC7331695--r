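test_that("gene values are overlap-weighted means of bin values", {
  # two bins of 1000 bp; prescribe segment ratios so the bin-level log2
  # values are exactly 1 and 0 (ploidy 2, baseline 2, minus the eps offset)
  eps <- 1e-3
  bins <- data.frame(chrom = "c1", start = c(0, 1000), end = c(1000, 2000),
                     gc = 0.45, mappability = 1)
  segs <- data.frame(chrom = "c1", start_bin = 1:2, end_bin = 1:2, n_bins = 1,
                     mean_ratio = c(2 - eps, 1 - eps))
  prof <- fake_profile(bins, segs)
  # gene inside one bin -> that bin's value
  g1 <- data.frame(chrom = "c1", start = 100, end = 300, name = "inside")
  expect_equal(unname(bins_to_genes(prof, g1)), 1)
  # gene overlapping the bins 75% / 25% -> 0.75
  g2 <- data.frame(chrom = "c1", start = 400, end = 1200, name = "spanning")
  expect_equal(unname(bins_to_genes(prof, g2)), 0.75)
  # gene on an absent chromosome -> missing
  g3 <- data.frame(chrom = "c9", start = 0, end = 100, name = "nowhere")
  expect_true(is.na(bins_to_genes(prof, g3)))
  expect_error(bins_to_genes(prof, g1[0, ]), "at least one")
})

test_that("gene values agree with a per-base brute-force oracle", {
  set.seed(8)
  bins <- data.frame(chrom = "c1", start = seq(0, 9900, 100),
                     end = seq(100, 10000, 100), gc = 0.45, mappability = 1)
  # majority of bins neutral so the modal-state baseline is unambiguously 2
  ratios <- sample(c(rep(1, 60), runif(40, 0.4, 2)))
  segs <- data.frame(chrom = "c1", start_bin = 1:100, end_bin = 1:100,
                     n_bins = 1, mean_ratio = ratios)
  prof <- fake_profile(bins, segs)
  binval <- pmin(pmax(log2(ratios * 2 / 2 + 1e-3), -3), 3)
  genes <- data.frame(chrom = "c1",
                      start = sample(0:9000, 30),
                      name = sprintf("g%02d", 1:30))
  genes$end <- genes$start + sample(50:900, 30)
  got <- bins_to_genes(prof, genes)
  want <- vapply(seq_len(nrow(genes)), function(k) {
    gene_value_oracle(bins, binval, genes[k, ])
  }, numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-9)
})

test_that("cytoband aggregation follows gene-midpoint membership", {
  bands <- data.frame(chrom = "c1", start = c(0, 1000), end = c(1000, 2000),
                      name = c("1p", "1q"))
  genes <- data.frame(chrom = "c1", start = c(0, 400, 950, 1500),
                      end = c(200, 600, 1150, 1700),
                      name = c("a", "b", "straddle", "d"))
  gv <- c(a = 0.5, b = -0.5, straddle = 2, d = 1)
  # gene "straddle" spans the boundary but its midpoint (1050) is in 1q
  out <- genes_to_cytobands(gv, genes, bands)
  expect_equal(unname(out["1p"]), 0)        # mean of 0.5 and -0.5
  expect_equal(unname(out["1q"]), 1.5)      # mean of 2 and 1
  # one gene per band -> identity
  out1 <- genes_to_cytobands(gv[c("a", "d")], genes[c(1, 4), ], bands)
  expect_equal(unname(out1), c(0.5, 1))
  # band with no gene -> missing; direct-membership oracle agreement
  empty <- data.frame(chrom = "c1", start = 5000, end = 6000, name = "void")
  expect_true(is.na(genes_to_cytobands(gv, genes, rbind(bands, empty))["void"]))
  mid <- (genes$start + genes$end) / 2
  for (b in seq_len(nrow(bands))) {
    members <- mid >= bands$start[b] & mid < bands$end[b]
    expect_equal(unname(out[bands$name[b]]), mean(gv[members]))
  }
})

test_that("ternary calls use strict thresholds and preserve missingness", {
  v <- c(0, 0.5, -0.4, 0.3, -0.3, NA)
  calls <- call_ternary(v, tau = 0.3)
  expect_equal(calls, c(0, 1, -1, 0, 0, NA))  # boundary values stay neutral
  expect_error(call_ternary(v, tau = 0), "tau")
  expect_error(call_ternary(v, tau = -1), "tau")
})

test_that("raising tau never increases the number of non-zero calls", {
  set.seed(12)
  v <- matrix(rnorm(500), 10)
  n_calls <- vapply(c(0.1, 0.3, 0.5, 1), function(tau) {
    sum(call_ternary(v, tau) != 0)
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("an all-neutral profile yields zero gene values and calls", {
  g <- test_genome()
  segs <- data.frame(chrom = unique(g$bins$chrom),
                     start_bin = which(!duplicated(g$bins$chrom)),
                     end_bin = which(!duplicated(g$bins$chrom, fromLast = TRUE)),
                     n_bins = as.vector(table(g$bins$chrom)[unique(g$bins$chrom)]),
                     mean_ratio = 1)
  prof <- fake_profile(g$bins, segs, ploidy = 2)
  gv <- bins_to_genes(prof, g$genes)
  expect_true(all(abs(gv) < 0.01))
  expect_true(all(call_ternary(gv, 0.3) == 0))
})

test_that("panel extraction keeps panel order and reports unknown loci", {
  m <- scna_matrix(matrix(1:10, 2, dimnames = list(NULL, paste0("b", 1:5))),
                   level = "cytoband")
  # identity
  all5 <- panel_extract(m, paste0("b", 1:5))
  expect_identical(all5$values, m$values)
  # one unknown of five -> warning naming it, 4 columns in panel order
  expect_warning(sub <- panel_extract(m, c("b4", "b2", "zz", "b1")), "zz")
  expect_identical(colnames(sub$values), c("b4", "b2", "b1"))
  expect_error(suppressWarnings(panel_extract(m, c("nope"))), "degenerate")
})

test_that("the shipped 59-locus panel restricts a matching matrix to 59 columns", {
  panel <- read.table(system.file("extdata", "synthetic_hcc_panel_59.tsv",
                                  package = "liquidSCNA"),
                      header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(panel), 59L)
  vals <- matrix(0, 2, nrow(panel) + 5)
  colnames(vals) <- c(panel$locus, paste0("extra", 1:5))
  m <- scna_matrix(vals, level = "cytoband")
  out <- panel_extract(m, panel)
  expect_equal(ncol(out$values), 59L)
})
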