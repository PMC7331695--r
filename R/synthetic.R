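#' Generate a synthetic genome with bins, genes and cytobands
#'
#' Builds the shared coordinate frame the rest of the pipeline operates on:
#' equally sized chromosomes tiled by fixed-width bins carrying a smooth GC
#' fraction and a mappability weight, plus named gene intervals and a cytoband
#' partition of every chromosome. Coordinates are 0-based half-open (BED
#' convention) throughout.
#'
#' GC content is drawn from an autocorrelated (AR(1)) process per chromosome
#' and squashed into \[0.3, 0.6\], emulating the smooth isochore-like GC
#' variation that drives amplification bias in whole-genome-amplified
#' low-pass sequencing. Mappability weights are drawn in (0, 1\].
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Chromosome length in bp; all chromosomes share it.
#' @param bin_size Bin width in bp (default 250 kb, the working resolution
#'   for few-cell copy-number profiling).
#' @param genes_per_chrom Number of gene intervals to place per chromosome.
#' @param bands_per_chrom Number of cytobands per chromosome; bands partition
#'   each chromosome exactly.
#' @param seed Integer seed; the genome is deterministic given the seed.
#' @return An object of class `synthetic_genome`: a list with data frames
#'   `chromosomes` (name, length), `bins` (chrom, start, end, gc,
#'   mappability), `genes` and `cytobands` (chrom, start, end, name).
#' @examples
#' g <- make_genome(2, 10e6, bin_size = 250e3, seed = 1)
#' nrow(g$bins)  # 80 bins
#' @export
make_genome <- function(n_chrom, chrom_length, bin_size = 250e3,
                        genes_per_chrom = 50L, bands_per_chrom = 8L,
                        seed = 1L) {
  stopifnot_scalar_count(n_chrom, "n_chrom")
  stopifnot_scalar_count(chrom_length, "chrom_length")
  stopifnot_scalar_count(bin_size, "bin_size")
  stopifnot_scalar_count(genes_per_chrom, "genes_per_chrom")
  stopifnot_scalar_count(bands_per_chrom, "bands_per_chrom")
  if (bin_size > chrom_length) {
    stop("`bin_size` must not exceed `chrom_length`", call. = FALSE)
  }

  with_seed(seed, {
    chroms <- data.frame(
      name = paste0("chr", seq_len(n_chrom)),
      length = rep(as.numeric(chrom_length), n_chrom),
      stringsAsFactors = FALSE
    )

    bins_per_chrom <- floor(chrom_length / bin_size)
    bin_list <- vector("list", n_chrom)
    gene_list <- vector("list", n_chrom)
    band_list <- vector("list", n_chrom)

    for (ci in seq_len(n_chrom)) {
      starts <- (seq_len(bins_per_chrom) - 1L) * bin_size
      ends <- starts + bin_size
      ends[bins_per_chrom] <- chrom_length  # absorb the remainder

      # smooth GC: AR(1) latent process mapped into [0.3, 0.6]
      z <- numeric(bins_per_chrom)
      z[1] <- rnorm(1)
      if (bins_per_chrom > 1) {
        eps <- rnorm(bins_per_chrom - 1L, sd = sqrt(1 - 0.9^2))
        for (k in 2:bins_per_chrom) z[k] <- 0.9 * z[k - 1L] + eps[k - 1L]
      }
      gc <- 0.45 + 0.15 * tanh(z / 2)

      mappability <- pmin(1, pmax(1e-3, 1 - stats::rbeta(bins_per_chrom, 1, 12)))

      bin_list[[ci]] <- data.frame(
        chrom = chroms$name[ci], start = starts, end = ends,
        gc = gc, mappability = mappability, stringsAsFactors = FALSE
      )

      glen <- round(runif(genes_per_chrom, 1e4, 2e5))
      gstart <- floor(runif(genes_per_chrom, 0, chrom_length - glen))
      gene_list[[ci]] <- data.frame(
        chrom = chroms$name[ci], start = gstart, end = gstart + glen,
        name = sprintf("G%d_%03d", ci, seq_len(genes_per_chrom)),
        stringsAsFactors = FALSE
      )

      # cytobands: random interior breakpoints partitioning the chromosome;
      # first half named p-arm, second half q-arm
      if (bands_per_chrom > 1) {
        brk <- sort(sample(seq(1e5, chrom_length - 1e5, by = 1e4),
                           bands_per_chrom - 1L))
      } else {
        brk <- numeric(0)
      }
      bstart <- c(0, brk)
      bend <- c(brk, chrom_length)
      half <- ceiling(bands_per_chrom / 2)
      arm <- c(rep("p", half), rep("q", bands_per_chrom - half))
      idx <- c(rev(seq_len(half)), seq_len(bands_per_chrom - half))
      band_list[[ci]] <- data.frame(
        chrom = chroms$name[ci], start = bstart, end = bend,
        name = paste0(ci, arm, idx), stringsAsFactors = FALSE
      )
    }

    out <- list(
      chromosomes = chroms,
      bins = do.call(rbind, bin_list),
      genes = do.call(rbind, gene_list),
      cytobands = do.call(rbind, band_list)
    )
    rownames(out$bins) <- NULL
    rownames(out$genes) <- NULL
    rownames(out$cytobands) <- NULL
    class(out) <- "synthetic_genome"
    out
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "synthetic_genome: %d chromosome(s), %d bins, %d genes, %d cytobands\n",
    nrow(x$chromosomes), nrow(x$bins), nrow(x$genes), nrow(x$cytobands)
  ))
  invisible(x)
}

#' Simulate a clonally related tumor/CTC pair of integer copy-number profiles
#'
#' Both profiles start diploid (state 2 everywhere). The tumor receives
#' `n_tumor_events` contiguous, non-overlapping altered runs with states drawn
#' from \{0, 1, 3, 4, 5, 6\}. The CTC reproduces a subset of tumor events whose
#' total bin count approximates `shared_fraction` of the tumor-altered bins
#' (event-level granularity), and additionally receives `n_private_events`
#' CTC-only events placed exclusively on tumor-neutral spans so the designed
#' shared fraction is not confounded.
#'
#' @param genome A `synthetic_genome`.
#' @param n_tumor_events Number of tumor alteration events.
#' @param shared_fraction Designed fraction of tumor-altered bins reproduced
#'   in the CTC, in \[0, 1\].
#' @param n_private_events Number of CTC-only events.
#' @param seed Integer seed.
#' @param event_len_bins Length-2 integer range of event widths in bins.
#' @param states Integer states available to events (baseline 2 excluded).
#' @return An object of class `clone_pair`: list with integer vectors
#'   `tumor_states` and `ctc_states` (one per bin), the designed
#'   `shared_fraction`, and data frames `tumor_events`, `private_events`.
#' @export
simulate_clone_pair <- function(genome, n_tumor_events, shared_fraction,
                                n_private_events = 0L, seed = 1L,
                                event_len_bins = c(20L, 40L),
                                states = c(0L, 1L, 3L, 4L, 5L, 6L)) {
  stopifnot(inherits(genome, "synthetic_genome"))
  stopifnot_scalar_count(n_tumor_events, "n_tumor_events", min = 0L)
  stopifnot_scalar_count(n_private_events, "n_private_events", min = 0L)
  stopifnot_fraction(shared_fraction, "shared_fraction")

  nb <- nrow(genome$bins)
  chrom_of <- genome$bins$chrom

  with_seed(seed, {
    tumor <- rep(2L, nb)
    occupied <- rep(FALSE, nb)  # bins already used by any event

    place_events <- function(n_events, allowed) {
      # allowed: logical per bin marking where events may be placed
      ev <- vector("list", n_events)
      lens <- seq(event_len_bins[1], event_len_bins[2])
      for (k in seq_len(n_events)) {
        len <- lens[sample.int(length(lens), 1L)]
        placed <- FALSE
        for (attempt in seq_len(500L)) {
          start <- sample.int(nb - len + 1L, 1L)
          idx <- start:(start + len - 1L)
          if (length(unique(chrom_of[idx])) != 1L) next
          if (any(!allowed[idx]) || any(occupied[idx])) next
          occupied[idx] <<- TRUE
          ev[[k]] <- data.frame(
            start_bin = start, end_bin = start + len - 1L,
            state = sample(states, 1L)
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place a non-overlapping event; genome too small ",
               "for the requested event count/width", call. = FALSE)
        }
      }
      do.call(rbind, ev)
    }

    tumor_events <- if (n_tumor_events > 0) {
      place_events(n_tumor_events, rep(TRUE, nb))
    } else {
      data.frame(start_bin = integer(), end_bin = integer(), state = integer())
    }
    if (n_tumor_events > 0) {
      for (k in seq_len(nrow(tumor_events))) {
        tumor[tumor_events$start_bin[k]:tumor_events$end_bin[k]] <-
          tumor_events$state[k]
      }
    }

    # choose the event subset whose bin total best matches shared_fraction
    ctc <- rep(2L, nb)
    shared_idx <- integer(0)
    if (n_tumor_events > 0) {
      lens <- tumor_events$end_bin - tumor_events$start_bin + 1L
      total <- sum(lens)
      k0 <- round(shared_fraction * n_tumor_events)
      sel <- rep(FALSE, n_tumor_events)
      if (k0 > 0) sel[sample.int(n_tumor_events, k0)] <- TRUE
      # local search: single swaps/toggles that pull the realized bin
      # fraction toward the design value
      objective <- function(s) abs(sum(lens[s]) / total - shared_fraction)
      repeat {
        best <- objective(sel)
        improved <- FALSE
        for (a in which(sel)) for (b in which(!sel)) {
          cand <- sel; cand[a] <- FALSE; cand[b] <- TRUE
          if (objective(cand) < best - 1e-12) {
            sel <- cand; best <- objective(sel); improved <- TRUE
          }
        }
        if (!improved) break
      }
      shared_idx <- which(sel)
      for (k in shared_idx) {
        ctc[tumor_events$start_bin[k]:tumor_events$end_bin[k]] <-
          tumor_events$state[k]
      }
    }

    private_events <- if (n_private_events > 0) {
      place_events(n_private_events, tumor == 2L)
    } else {
      data.frame(start_bin = integer(), end_bin = integer(), state = integer())
    }
    if (n_private_events > 0) {
      for (k in seq_len(nrow(private_events))) {
        ctc[private_events$start_bin[k]:private_events$end_bin[k]] <-
          private_events$state[k]
      }
    }

    tumor_events$shared <- seq_len(nrow(tumor_events)) %in% shared_idx
    out <- list(
      tumor_states = tumor, ctc_states = ctc,
      shared_fraction = shared_fraction,
      tumor_events = tumor_events, private_events = private_events
    )
    class(out) <- "clone_pair"
    out
  })
}

#' @export
print.clone_pair <- function(x, ...) {
  altered <- sum(x$tumor_states != 2L)
  match <- if (altered > 0) {
    mean(x$ctc_states[x$tumor_states != 2L] == x$tumor_states[x$tumor_states != 2L])
  } else NA_real_
  cat(sprintf(
    "clone_pair: %d bins, %d tumor events (%d altered bins), designed shared %.2f, realized %.3f, %d private CTC events\n",
    length(x$tumor_states), nrow(x$tumor_events), altered,
    x$shared_fraction, match, nrow(x$private_events)
  ))
  invisible(x)
}

# Multiplicative log-quadratic amplification-bias curve: unimodal in GC with
# a peak location and curvature, the shape loess correction is built to remove.
gc_bias_curve <- function(gc, params) {
  peak <- if (!is.null(params$peak)) params$peak else 0.45
  curvature <- if (!is.null(params$curvature)) params$curvature else 10
  exp(-curvature * (gc - peak)^2)
}

#' Simulate binned low-pass read counts from an integer copy-number profile
#'
#' Expected reads per bin are proportional to
#' `state * bin_length * mappability * bias(gc)` where the bias is a
#' multiplicative log-quadratic curve in GC (parameters `peak`, `curvature`),
#' normalized so expectations sum to `total_reads`. Counts are Poisson when
#' `dispersion = 0` and negative binomial otherwise, modeling
#' whole-genome-amplification overdispersion as a Gamma-distributed per-bin
#' amplification factor whose coefficient of variation is `dispersion`
#' (so `Var = mu + (dispersion * mu)^2`).
#'
#' @param genome A `synthetic_genome`.
#' @param states Integer copy state per bin (>= 0), length `nrow(genome$bins)`.
#' @param total_reads Total expected read count (> 0).
#' @param gc_bias_params List with `peak` (GC of maximal amplification,
#'   default 0.45) and `curvature` (default 10; 0 disables the bias).
#' @param dispersion Amplification-noise CV (>= 0; 0 = Poisson).
#' @param seed Integer seed.
#' @return An object of class `read_counts`: list with integer `counts` per
#'   bin, `total_reads`, `gc_bias_params` and `dispersion`.
#' @export
simulate_reads <- function(genome, states, total_reads,
                           gc_bias_params = list(peak = 0.45, curvature = 10),
                           dispersion = 0, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  nb <- nrow(genome$bins)
  if (length(states) != nb || any(states < 0) || any(states != floor(states))) {
    stop("`states` must be non-negative integers, one per bin", call. = FALSE)
  }
  if (!is.numeric(total_reads) || length(total_reads) != 1L || total_reads <= 0) {
    stop("`total_reads` must be a single positive number", call. = FALSE)
  }
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)

  blen <- genome$bins$end - genome$bins$start
  w <- states * blen * genome$bins$mappability *
    gc_bias_curve(genome$bins$gc, gc_bias_params)
  if (sum(w) <= 0) stop("all bins have zero expected coverage", call. = FALSE)
  mu <- total_reads * w / sum(w)

  counts <- with_seed(seed, {
    if (dispersion == 0) {
      rpois(nb, mu)
    } else {
      rnbinom(nb, size = 1 / dispersion^2, mu = mu)
    }
  })
  counts[mu == 0] <- 0L

  out <- list(counts = as.integer(counts), total_reads = total_reads,
              gc_bias_params = gc_bias_params, dispersion = dispersion)
  class(out) <- "read_counts"
  out
}

#' Construct a class-signature set for cohort simulation
#'
#' A signature set lists, per cancer class, the recurrent alterations that
#' define it: a cytoband (or arm-prefix) span, a direction, a prevalence and
#' a mean amplitude. It is the generative counterpart of the recurrent,
#' class-specific SCNA structure a cytoband feature matrix carries.
#'
#' @param cytobands Character vector: the cytoband universe (unique names).
#' @param events_by_class Named list (one element per class) of data frames
#'   with columns `span` (cytoband name or arm prefix such as "3p"),
#'   `direction` ("gain" or "loss"), `prevalence` in \[0,1\], `amplitude` > 0.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(cytobands, events_by_class) {
  cytobands <- as.character(cytobands)
  if (anyDuplicated(cytobands)) stop("duplicate cytoband names", call. = FALSE)
  if (length(events_by_class) == 0 || is.null(names(events_by_class)) ||
      any(!nzchar(names(events_by_class)))) {
    stop("`events_by_class` must be a non-empty named list", call. = FALSE)
  }
  for (cl in names(events_by_class)) {
    ev <- events_by_class[[cl]]
    if (!is.data.frame(ev) || nrow(ev) < 1) {
      stop(sprintf("class '%s' must have >= 1 event", cl), call. = FALSE)
    }
    stopifnot(all(c("span", "direction", "prevalence", "amplitude") %in% names(ev)))
    if (any(ev$prevalence < 0 | ev$prevalence > 1)) {
      stop("prevalences must be in [0, 1]", call. = FALSE)
    }
    if (any(ev$amplitude <= 0)) stop("amplitudes must be > 0", call. = FALSE)
    if (!all(ev$direction %in% c("gain", "loss"))) {
      stop("direction must be 'gain' or 'loss'", call. = FALSE)
    }
    for (sp in ev$span) {
      if (length(resolve_span(sp, cytobands)) == 0) {
        stop(sprintf("event span '%s' resolves to no cytoband", sp), call. = FALSE)
      }
    }
  }
  structure(list(classes = names(events_by_class), cytobands = cytobands,
                 events = events_by_class),
            class = "signature_set")
}

# A span is either an exact cytoband name or an arm prefix ("1p" matches
# "1p1", "1p2", ...).
resolve_span <- function(span, cytobands) {
  hit <- cytobands == span
  if (any(hit)) return(which(hit))
  which(startsWith(cytobands, span))
}

#' Draw a random signature set over a cytoband universe
#'
#' Convenience generator for simulation studies: each class receives
#' `events_per_class` events at cytobands sampled without replacement within
#' the class, random directions, and amplitudes around `amplitude`. Classes
#' may be forced to share a fraction of their events via `shared_events`
#' (a list of class-pairs), which is how "biologically similar" classes are
#' emulated.
#'
#' @param cytobands Cytoband universe.
#' @param classes Character vector of class labels.
#' @param events_per_class Events per class.
#' @param prevalence Event prevalence (scalar, applied to all events).
#' @param amplitude Mean absolute amplitude (log2-ratio-like units).
#' @param seed Integer seed.
#' @return A `signature_set`.
#' @export
random_signature_set <- function(cytobands, classes, events_per_class = 6L,
                                 prevalence = 1, amplitude = 1, seed = 1L) {
  stopifnot(length(classes) >= 1, length(cytobands) >= events_per_class)
  with_seed(seed, {
    ev <- lapply(classes, function(cl) {
      bands <- sample(cytobands, events_per_class)
      data.frame(
        span = bands,
        direction = sample(c("gain", "loss"), events_per_class, replace = TRUE),
        prevalence = prevalence,
        amplitude = pmax(0.2, amplitude * runif(events_per_class, 0.8, 1.2)),
        stringsAsFactors = FALSE
      )
    })
    names(ev) <- classes
    signature_set(cytobands, ev)
  })
}

#' Simulate a multi-class cytoband-level SCNA cohort
#'
#' Per sample, each event of its class is present with its prevalence; when
#' present it adds `direction`-signed `Normal(amplitude, noise_sd)` to the
#' event's cytobands. Passenger events (random cytoband, random sign) occur
#' at rate `passenger_rate` per sample, and Gaussian background noise
#' `Normal(0, noise_sd)` covers the whole matrix.
#'
#' @param signatures A `signature_set`.
#' @param samples_per_class Samples simulated for every class.
#' @param passenger_rate Expected passenger events per sample (Poisson).
#' @param noise_sd Background/amplitude noise SD (log2-ratio-like units).
#' @param passenger_amplitude Mean absolute passenger amplitude.
#' @param seed Integer seed.
#' @return An `scna_matrix` (level "cytoband") with per-sample class labels.
#' @export
simulate_cohort <- function(signatures, samples_per_class, passenger_rate = 1,
                            noise_sd = 0.2, passenger_amplitude = 0.6,
                            seed = 1L) {
  if (!inherits(signatures, "signature_set")) {
    stop("`signatures` must be a signature_set", call. = FALSE)
  }
  stopifnot_scalar_count(samples_per_class, "samples_per_class")
  bands <- signatures$cytobands
  nb <- length(bands)
  classes <- signatures$classes
  n <- samples_per_class * length(classes)

  with_seed(seed, {
    values <- matrix(rnorm(n * nb, 0, noise_sd), nrow = n, ncol = nb,
                     dimnames = list(NULL, bands))
    labels <- rep(classes, each = samples_per_class)
    for (i in seq_len(n)) {
      ev <- signatures$events[[labels[i]]]
      for (k in seq_len(nrow(ev))) {
        if (runif(1) <= ev$prevalence[k]) {
          sgn <- if (ev$direction[k] == "gain") 1 else -1
          idx <- resolve_span(ev$span[k], bands)
          values[i, idx] <- values[i, idx] +
            sgn * rnorm(1, ev$amplitude[k], noise_sd)
        }
      }
      npass <- rpois(1, passenger_rate)
      if (npass > 0) {
        idx <- sample.int(nb, min(npass, nb))
        values[i, idx] <- values[i, idx] +
          sample(c(-1, 1), length(idx), replace = TRUE) *
            rnorm(length(idx), passenger_amplitude, noise_sd)
      }
    }
    rownames(values) <- sprintf("S%04d", seq_len(n))
    scna_matrix(values, level = "cytoband", labels = labels)
  })
}
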