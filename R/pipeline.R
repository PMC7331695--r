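#' Default demonstration pipeline configuration
#'
#' The demo emulates the study design at desk scale: nine patients with a
#' matched tumor/CTC pair each (high designed concordance), low-pass
#' GC-biased read counts per sample, and a five-class cytoband cohort of 100
#' samples per class for the tissue-of-origin model, plus a small query
#' cohort standing in for CTC samples to classify. Every stochastic stage
#' carries an explicit seed.
#'
#' @param seed Base seed; per-stage seeds are derived from it.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seeds = list(
      genome = seed, pairs = seed + 1L, reads = seed + 2L,
      segmentation = seed + 3L, signatures = seed + 4L, cohort = seed + 5L,
      model = seed + 6L, query = seed + 7L
    ),
    genome = list(n_chrom = 6L, chrom_length = 5e7, bin_size = 250e3,
                  genes_per_chrom = 80L, bands_per_chrom = 8L),
    patients = list(n = 9L, shared_fraction = 0.9, n_tumor_events = 10L,
                    n_private_events = 1L, event_len_bins = c(20L, 40L)),
    reads = list(total = 1e6, dispersion = 0.3, gc_peak = 0.45,
                 gc_curvature = 10),
    profiling = list(span = 0.3, alpha = 0.01, nperm = 1000L, min_width = 3L),
    calls = list(tau = 0.3),
    cohort = list(n_classes = 5L, samples_per_class = 100L,
                  events_per_class = 6L, prevalence = 0.95, amplitude = 1,
                  noise_sd = 0.2, passenger_rate = 1),
    classifier = list(n_trees = 500L, split = 0.8, cv_folds = 5L,
                      cv_repeats = 3L, elimination_threshold = 0.5,
                      k_embed = 15L, perplexity = 30, tsne_iter = 1000L),
    query = list(per_class = 3L)
  )
}

#' Read and validate a pipeline configuration file
#'
#' @param path YAML file with the structure of
#'   [default_pipeline_config()].
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Checks, before any compute, that every stochastic stage has an explicit
#' seed and that all required sections are present.
#'
#' @param config Configuration list.
#' @return The configuration, invisibly, or an error.
#' @export
validate_pipeline_config <- function(config) {
  need_seeds <- c("genome", "pairs", "reads", "segmentation", "signatures",
                  "cohort", "model", "query")
  missing <- setdiff(need_seeds, names(config$seeds))
  bad <- names(config$seeds)[vapply(config$seeds, function(s)
    !is.numeric(s) || length(s) != 1L || is.na(s), logical(1))]
  if (length(missing) > 0 || length(bad) > 0) {
    stop("validation error: missing or invalid seed(s): ",
         paste(unique(c(missing, bad)), collapse = ", "), call. = FALSE)
  }
  sections <- c("genome", "patients", "reads", "profiling", "calls",
                "cohort", "classifier", "query")
  absent <- setdiff(sections, names(config))
  if (length(absent) > 0) {
    stop("validation error: missing config section(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

#' Run the full demonstration pipeline
#'
#' Simulate -> profile -> call -> concordance -> train -> classify, writing
#' every intermediate artifact plus a single `summary.json` of headline
#' statistics (median sensitivity and specificity, shared-fraction summary,
#' pair co-clustering count, model accuracy, per-class balanced accuracy,
#' query classification rate) to `out_dir`. The run is fully reproducible
#' from the configuration and its seeds; `summary.json` is byte-identical
#' across reruns. A `log.txt` records the package version, a config hash and
#' per-stage wall time (kept apart from the summary so timing noise cannot
#' break reproducibility).
#'
#' @param config Configuration list (see [default_pipeline_config()]) or the
#'   path of a YAML file.
#' @param out_dir Output directory.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("liquidSCNA %s | R %s\nconfig md5: %s\n",
              as.character(utils::packageVersion("liquidSCNA")),
              paste(R.version$major, R.version$minor, sep = "."),
              unname(tools::md5sum(cfg_path))),
      file = log_path)

  stages <- character(0)
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    cat(sprintf("stage %-12s %8.2f s\n", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        file = log_path, append = TRUE)
    res
  }

  # --- simulate genome -------------------------------------------------
  genome <- run_stage("genome", function() {
    g <- do.call(make_genome, c(config$genome, list(seed = config$seeds$genome)))
    write_genome(g, file.path(out_dir, "genome"))
    g
  })

  # --- patients: clone pairs, reads, profiles --------------------------
  pp <- config$patients
  rr <- config$reads
  pf <- config$profiling
  samples <- run_stage("profiles", function() {
    out <- list()
    for (i in seq_len(pp$n)) {
      pair <- simulate_clone_pair(
        genome, n_tumor_events = pp$n_tumor_events,
        shared_fraction = pp$shared_fraction,
        n_private_events = pp$n_private_events,
        seed = config$seeds$pairs + i,
        event_len_bins = if (!is.null(pp$event_len_bins)) pp$event_len_bins
                         else c(20L, 40L)
      )
      for (role in c("tumor", "ctc")) {
        states <- if (role == "tumor") pair$tumor_states else pair$ctc_states
        sid <- sprintf("P%02d_%s", i, role)
        reads <- simulate_reads(
          genome, states, total_reads = rr$total,
          gc_bias_params = list(peak = rr$gc_peak, curvature = rr$gc_curvature),
          dispersion = rr$dispersion,
          seed = config$seeds$reads + 10L * i + (role == "ctc")
        )
        write_counts(reads, file.path(out_dir, paste0(sid, ".counts.tsv")))
        prof <- profile_sample(
          genome, reads, sample_id = sid, span = pf$span, alpha = pf$alpha,
          nperm = pf$nperm, min_width = pf$min_width,
          seed = config$seeds$segmentation + 10L * i + (role == "ctc")
        )
        write_seg(prof, file.path(out_dir, paste0(sid, ".seg")))
        out[[sid]] <- list(profile = prof, true_states = states, patient = i,
                           role = role)
      }
    }
    out
  })

  # --- gene-level calls and concordance --------------------------------
  tau <- config$calls$tau
  conc <- run_stage("concordance", function() {
    gene_vals <- sapply(samples, function(s) bins_to_genes(s$profile, genome$genes))
    gene_vals <- t(gene_vals)  # samples x genes
    gmat <- add_calls(
      scna_matrix(gene_vals, level = "gene", features = genome$genes),
      tau = tau
    )
    write_scna_matrix(gmat, file.path(out_dir, "gene_matrix.tsv"))

    reports <- do.call(rbind, lapply(seq_len(pp$n), function(i) {
      cid <- sprintf("P%02d_ctc", i)
      tid <- sprintf("P%02d_tumor", i)
      pair_concordance(gmat$calls[cid, ], gmat$calls[tid, ],
                       gmat$values[cid, ], gmat$values[tid, ],
                       pair_id = sprintf("P%02d", i))
    }))
    write.table(reports, file.path(out_dir, "concordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    pairs <- data.frame(ctc = sprintf("P%02d_ctc", seq_len(pp$n)),
                        tumor = sprintf("P%02d_tumor", seq_len(pp$n)))
    vals <- gmat$values
    vals[is.na(vals)] <- 0
    cl <- cluster_samples(vals, pairs = pairs)
    writeLines(cl$newick, file.path(out_dir, "dendrogram.nwk"))
    write.table(cl$co_membership, file.path(out_dir, "co_membership.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(reports = reports, clustering = cl)
  })

  # --- cohort + origin model -------------------------------------------
  ch <- config$cohort
  cls <- config$classifier
  classes <- paste0("class", seq_len(ch$n_classes))
  sigs <- random_signature_set(genome$cytobands$name, classes,
                               events_per_class = ch$events_per_class,
                               prevalence = ch$prevalence,
                               amplitude = ch$amplitude,
                               seed = config$seeds$signatures)
  model <- run_stage("train", function() {
    cohort <- simulate_cohort(sigs, samples_per_class = ch$samples_per_class,
                              passenger_rate = ch$passenger_rate,
                              noise_sd = ch$noise_sd,
                              seed = config$seeds$cohort)
    write_scna_matrix(cohort, file.path(out_dir, "cohort.tsv"))
    ft <- build_features(cohort, whitelist = genome$cytobands$name,
                         perplexity = cls$perplexity, n_iter = cls$tsne_iter,
                         seed = config$seeds$model)
    m <- train_origin_model(
      ft, n_trees = cls$n_trees, split = cls$split,
      cv = list(folds = cls$cv_folds, repeats = cls$cv_repeats),
      elimination_threshold = cls$elimination_threshold,
      k_embed = cls$k_embed, seed = config$seeds$model
    )
    save_origin_model(m, file.path(out_dir, "origin_model"))
    m
  })

  # --- classify a fresh query cohort (the CTC stand-in) ------------------
  query <- run_stage("classify", function() {
    qc <- simulate_cohort(sigs, samples_per_class = config$query$per_class,
                          passenger_rate = ch$passenger_rate,
                          noise_sd = ch$noise_sd,
                          seed = config$seeds$query)
    pred <- classify_samples(model, qc)
    res <- cbind(pred$predictions, truth = qc$labels)
    write.table(res, file.path(out_dir, "query_classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(accuracy = mean(pred$predictions$predicted == qc$labels),
         n = nrow(pred$predictions))
  })

  reports <- conc$reports
  summary <- list(
    n_patients = pp$n,
    median_sensitivity = median(reports$sensitivity, na.rm = TRUE),
    median_specificity = median(reports$specificity, na.rm = TRUE),
    mean_shared_fraction = mean(reports$shared_fraction, na.rm = TRUE),
    median_shared_fraction = median(reports$shared_fraction, na.rm = TRUE),
    median_pearson_r = median(reports$pearson_r, na.rm = TRUE),
    pairs_co_clustered = sum(conc$clustering$co_membership$co_clustered),
    n_pairs = nrow(conc$clustering$co_membership),
    model_overall_accuracy = model$accuracy$overall,
    per_class_balanced_accuracy = as.list(model$accuracy$per_class_balanced),
    n_types_eliminated = length(model$eliminated),
    query_classification_accuracy = query$accuracy,
    n_query_samples = query$n
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
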