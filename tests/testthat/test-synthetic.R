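test_that("make_genome tiles chromosomes with the requested bins", {
  g <- make_genome(1, 10e6, 250e3, seed = 1)
  expect_equal(nrow(g$bins), 40L)  # 10e6 / 250e3
  expect_true(all(g$bins$end > g$bins$start))
  # bins tile each chromosome without gaps
  for (ch in g$chromosomes$name) {
    b <- g$bins[g$bins$chrom == ch, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], g$chromosomes$length[g$chromosomes$name == ch])
    if (nrow(b) > 1) expect_equal(b$start[-1], b$end[-nrow(b)])
  }
  expect_true(all(g$bins$gc >= 0.3 & g$bins$gc <= 0.6))
  expect_true(all(g$bins$mappability > 0 & g$bins$mappability <= 1))
})

test_that("cytobands partition chromosomes exactly", {
  g <- make_genome(2, 5e6, 250e3, bands_per_chrom = 4, seed = 3)
  expect_equal(nrow(g$cytobands), 8L)
  for (ch in g$chromosomes$name) {
    b <- g$cytobands[g$cytobands$chrom == ch, ]
    b <- b[order(b$start), ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], 5e6)
    expect_equal(b$start[-1], b$end[-nrow(b)])  # disjoint and covering
  }
  expect_false(anyDuplicated(g$cytobands$name) > 0)
})

test_that("every gene overlaps at least one bin", {
  g <- test_genome()
  for (k in seq_len(nrow(g$genes))) {
    on <- g$bins$chrom == g$genes$chrom[k]
    ov <- pmin(g$bins$end[on], g$genes$end[k]) -
      pmax(g$bins$start[on], g$genes$start[k])
    expect_true(any(ov > 0))
  }
})

test_that("generators are deterministic given the seed", {
  g1 <- make_genome(2, 5e6, 250e3, seed = 7)
  g2 <- make_genome(2, 5e6, 250e3, seed = 7)
  expect_identical(g1, g2)

  p1 <- simulate_clone_pair(g1, 4, 0.5, 1, seed = 9, event_len_bins = c(2, 3))
  p2 <- simulate_clone_pair(g1, 4, 0.5, 1, seed = 9, event_len_bins = c(2, 3))
  expect_identical(p1, p2)

  r1 <- simulate_reads(g1, p1$tumor_states, 1e5, dispersion = 0.3, seed = 5)
  r2 <- simulate_reads(g1, p1$tumor_states, 1e5, dispersion = 0.3, seed = 5)
  expect_identical(r1, r2)

  sigs <- random_signature_set(g1$cytobands$name, c("a", "b"), 3, seed = 2)
  c1 <- simulate_cohort(sigs, 5, seed = 4)
  c2 <- simulate_cohort(sigs, 5, seed = 4)
  expect_identical(c1, c2)
})

test_that("make_genome rejects degenerate arguments", {
  expect_error(make_genome(0, 1e6, 1e5), "n_chrom")
  expect_error(make_genome(1, 1e6, 2e6), "bin_size")
  expect_error(make_genome(1, -5, 1e5), "chrom_length")
})

test_that("clone pairs honor the designed shared fraction at event level", {
  g <- study_genome()
  # full sharing, no private events -> identical profiles
  p <- simulate_clone_pair(g, 8, 1, 0, seed = 1)
  expect_identical(p$ctc_states, p$tumor_states)
  # no sharing -> no tumor-altered bin altered in the CTC
  p0 <- simulate_clone_pair(g, 8, 0, 2, seed = 2)
  alt <- p0$tumor_states != 2L
  expect_true(all(p0$ctc_states[alt] == 2L))
  # 0.8 with 10 equal-length events -> exactly 8 events reproduced
  p8 <- simulate_clone_pair(g, 10, 0.8, 0, seed = 3, event_len_bins = c(20, 20))
  expect_equal(sum(p8$tumor_events$shared), 8L)
  alt <- p8$tumor_states != 2L
  expect_equal(mean(p8$ctc_states[alt] == p8$tumor_states[alt]), 0.8)
})

test_that("private CTC events sit only on tumor-neutral spans", {
  g <- study_genome()
  for (s in 1:5) {
    p <- simulate_clone_pair(g, 10, 0.5, 3, seed = s)
    for (k in seq_len(nrow(p$private_events))) {
      idx <- p$private_events$start_bin[k]:p$private_events$end_bin[k]
      expect_true(all(p$tumor_states[idx] == 2L))
    }
  }
})

test_that("shared_fraction outside [0,1] is rejected", {
  g <- test_genome()
  expect_error(simulate_clone_pair(g, 3, 1.2, 0), "shared_fraction")
  expect_error(simulate_clone_pair(g, 3, -0.1, 0), "shared_fraction")
})

test_that("read expectations scale with state, length, mappability", {
  g <- make_genome(1, 20e6, 250e3, seed = 5)
  g$bins$mappability <- 1  # equalize
  states <- rep(2L, nrow(g$bins))
  states[1:20] <- 4L
  r <- simulate_reads(g, states, 5e6, gc_bias_params = list(curvature = 0),
                      dispersion = 0, seed = 2)
  m4 <- mean(r$counts[1:20])
  m2 <- mean(r$counts[41:80])
  expect_lt(abs(m4 / m2 - 2), 0.1)
  # zero-state bins get zero counts
  states0 <- states; states0[30:35] <- 0L
  r0 <- simulate_reads(g, states0, 5e6, dispersion = 0.3, seed = 3)
  expect_true(all(r0$counts[30:35] == 0L))
  expect_error(simulate_reads(g, states, -1), "total_reads")
})

test_that("total read counts are Poisson-consistent over seeds", {
  g <- make_genome(1, 10e6, 250e3, seed = 6)
  states <- rep(2L, nrow(g$bins))
  total <- 2e5
  sums <- vapply(1:100, function(s) {
    sum(simulate_reads(g, states, total, dispersion = 0, seed = s)$counts)
  }, numeric(1))
  # mean of 100 Poisson(total) draws: SE = sqrt(total/100)
  expect_lt(abs(mean(sums) - total), 3 * sqrt(total / 100))
})

test_that("GC bias imprints the designed unimodal distortion", {
  g <- study_genome()
  states <- rep(2L, nrow(g$bins))
  r <- simulate_reads(g, states, 1e6,
                      gc_bias_params = list(peak = 0.45, curvature = 10),
                      dispersion = 0, seed = 21)
  dens <- r$counts / ((g$bins$end - g$bins$start) * g$bins$mappability)
  rho <- cor(dens, abs(g$bins$gc - 0.45), method = "spearman")
  expect_lt(rho, -0.3)  # strongly negative: far from the peak means fewer reads
  expect_lt(cor.test(dens, abs(g$bins$gc - 0.45), method = "spearman",
                     exact = FALSE)$p.value, 1e-6)
})

test_that("cohort simulation produces the designed class structure", {
  bands <- sprintf("b%02d", 1:30)
  sigs <- random_signature_set(bands, c("x", "y"), events_per_class = 4,
                               prevalence = 1, seed = 1)
  # deterministic limit: no noise, no passengers -> identical rows per class
  coh <- simulate_cohort(sigs, 4, passenger_rate = 0, noise_sd = 0, seed = 2)
  for (cl in c("x", "y")) {
    rows <- coh$values[coh$labels == cl, ]
    expect_true(all(apply(rows, 2, function(v) length(unique(v)) == 1)))
  }
  expect_equal(dim(coh$values), c(8L, 30L))
  # zero prevalence -> pure background noise
  sigs0 <- signature_set(bands, list(
    x = data.frame(span = "b01", direction = "gain", prevalence = 0, amplitude = 1),
    y = data.frame(span = "b02", direction = "loss", prevalence = 0, amplitude = 1)
  ))
  coh0 <- simulate_cohort(sigs0, 50, passenger_rate = 0, noise_sd = 0.3, seed = 3)
  expect_lt(abs(mean(coh0$values)), 0.02)
  expect_lt(abs(sd(coh0$values) - 0.3), 0.02)
})

test_that("signature sets validate their invariants", {
  bands <- c("1p1", "1p2", "1q1")
  expect_error(signature_set(bands, list()), "named list")
  expect_error(signature_set(bands, list(a = data.frame(
    span = "9q9", direction = "gain", prevalence = 1, amplitude = 1
  ))), "resolves to no cytoband")
  expect_error(signature_set(bands, list(a = data.frame(
    span = "1p1", direction = "gain", prevalence = 2, amplitude = 1
  ))), "prevalence")
  # arm prefixes resolve to every matching band
  s <- signature_set(bands, list(a = data.frame(
    span = "1p", direction = "gain", prevalence = 1, amplitude = 1
  )))
  coh <- simulate_cohort(s, 2, passenger_rate = 0, noise_sd = 0, seed = 1)
  expect_true(all(coh$values[, c("1p1", "1p2")] > 0))
  expect_true(all(coh$values[, "1q1"] == 0))
})
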