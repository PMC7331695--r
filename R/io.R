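# Readers and writers for the plain-text formats the pipeline exchanges:
# BED intervals, per-bin count TSVs, SEG segment tables and SCNA matrices
# (TSV + JSON sidecar). All coordinates are 0-based half-open on disk unless
# the 1-based dialect flag is set.

#' Read a BED-like interval file
#'
#' @param path File path. Tab-separated, no header: chrom, start, end, then
#'   optionally name and two numeric columns (the bins writer stores gc and
#'   mappability there).
#' @param one_based Set `TRUE` for 1-based inclusive input; starts are then
#'   shifted down by one to the internal 0-based half-open convention.
#' @return Data frame with `chrom`, `start`, `end` and any of `name`, `gc`,
#'   `mappability` present in the file.
#' @export
read_bed <- function(path, one_based = FALSE) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3) stop("BED needs >= 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(raw[[1]]),
                    start = as.numeric(raw[[2]]),
                    end = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
  if (one_based) out$start <- out$start - 1
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    stop(sprintf("parse error: end <= start at line %s of %s",
                 paste(bad, collapse = ", "), path), call. = FALSE)
  }
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$gc <- as.numeric(raw[[5]])
  if (ncol(raw) >= 6) out$mappability <- as.numeric(raw[[6]])
  out
}

#' Write intervals as BED
#'
#' Writes chrom/start/end plus, when present, a name column and the gc and
#' mappability columns (reusing BED columns 5 and 6).
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `gc`, `mappability`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, format(intervals$start, scientific = FALSE,
                                       trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) cols <- c(cols, list(intervals$name))
  if (!is.null(intervals$gc)) cols <- c(cols, list(intervals$gc))
  if (!is.null(intervals$mappability)) cols <- c(cols, list(intervals$mappability))
  write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a synthetic genome's annotation as BED files
#'
#' @param genome A `synthetic_genome`.
#' @param dir Output directory (created if needed); writes `bins.bed`
#'   (with gc and mappability in columns 5-6), `genes.bed`, `cytobands.bed`.
#' @return The directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins <- genome$bins
  bins$name <- sprintf("bin%05d", seq_len(nrow(bins)))
  write_bed(bins[, c("chrom", "start", "end", "name", "gc", "mappability")],
            file.path(dir, "bins.bed"))
  write_bed(genome$genes, file.path(dir, "genes.bed"))
  write_bed(genome$cytobands, file.path(dir, "cytobands.bed"))
  invisible(dir)
}

#' Write per-bin read counts keyed by bin id
#'
#' @param counts Integer vector or `read_counts` object.
#' @param path Output TSV path (columns `bin`, `count`).
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "read_counts")) counts <- counts$counts
  write.table(
    data.frame(bin = sprintf("bin%05d", seq_along(counts)), count = counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read per-bin read counts
#'
#' @param path TSV with columns `bin`, `count` (bins in genome order).
#' @return Integer vector of counts.
#' @export
read_counts_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  as.integer(tab$count)
}

#' Write a profile's segments in SEG format
#'
#' Standard SEG dialect: `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean` where `seg.mean` is the log2 ratio; the linear mean ratio is
#' kept in a `ratio` side column.
#'
#' @param profile A `cn_profile`.
#' @param path Output path.
#' @export
write_seg <- function(profile, path) {
  segs <- profile$segments
  bins <- profile$bins
  tab <- data.frame(
    ID = profile$sample_id,
    chrom = segs$chrom,
    loc.start = bins$start[segs$start_bin],
    loc.end = bins$end[segs$end_bin],
    num.mark = segs$n_bins,
    seg.mean = segs$seg_log2,
    ratio = segs$mean_ratio,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file
#'
#' @param path SEG file as written by [write_seg()] (a `ratio` side column is
#'   optional; when absent it is reconstructed from `seg.mean`).
#' @return Data frame with the SEG columns.
#' @export
read_seg <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  if (!all(need %in% names(tab))) {
    stop("not a SEG file: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  bad <- which(tab$loc.end <= tab$loc.start)
  if (length(bad) > 0) {
    stop(sprintf("parse error: loc.end <= loc.start at line %s of %s",
                 paste(bad, collapse = ", "), path), call. = FALSE)
  }
  if (is.null(tab$ratio)) tab$ratio <- 2^tab$seg.mean
  tab
}

#' Write an SCNA matrix as TSV with a JSON sidecar
#'
#' The TSV holds one sample per row: `sample`, `label` (empty when absent)
#' and one column per feature. The sidecar (`<path>.json`) records the level,
#' the call threshold and the feature intervals so the matrix round-trips
#' losslessly.
#'
#' @param x An `scna_matrix`.
#' @param path Output TSV path.
#' @export
write_scna_matrix <- function(x, path) {
  stopifnot(inherits(x, "scna_matrix"))
  tab <- data.frame(sample = rownames(x$values),
                    label = if (is.null(x$labels)) "" else x$labels,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(x$values, check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(level = x$level, tau = x$tau,
               features = x$features,
               has_calls = !is.null(x$calls))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(x$calls)) {
    ctab <- cbind(tab[, 1:2], as.data.frame(x$calls, check.names = FALSE))
    write.table(ctab, paste0(path, ".calls"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read an SCNA matrix written by [write_scna_matrix()]
#'
#' @param path TSV path (the `.json` sidecar and `.calls` file, when present,
#'   are picked up automatically).
#' @return An `scna_matrix`.
#' @export
read_scna_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(values) <- tab$sample
  labels <- if (all(is.na(tab$label)) || all(tab$label == "")) NULL else tab$label
  meta_path <- paste0(path, ".json")
  level <- "cytoband"; tau <- NA_real_; features <- NULL; calls <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    level <- meta$level
    tau <- if (is.null(meta$tau)) NA_real_ else meta$tau
    if (!is.null(meta$features) && length(meta$features) > 0) {
      features <- as.data.frame(meta$features)
    }
    if (isTRUE(meta$has_calls) && file.exists(paste0(path, ".calls"))) {
      ctab <- read.table(paste0(path, ".calls"), sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
      calls <- as.matrix(ctab[, -(1:2), drop = FALSE])
      rownames(calls) <- ctab$sample
    }
  }
  scna_matrix(values, level = level, features = features, labels = labels,
              calls = calls, tau = tau)
}

#' Serialize a trained origin model to a directory
#'
#' Writes human-readable JSON metadata (whitelist, class map, eliminated
#' types, tuned parameters, seed, accuracy summary), the embedding reference
#' set as TSV, and the forest in R's standard serialized form (`forest.rds`).
#' The JSON metadata plus the training configuration are sufficient to
#' retrain the bundle from scratch with [train_origin_model()] on another
#' platform.
#'
#' @param model An `origin_model`.
#' @param dir Output directory.
#' @export
save_origin_model <- function(model, dir) {
  stopifnot(inherits(model, "origin_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(whitelist = model$whitelist, class_map = as.list(model$class_map),
               eliminated = model$eliminated, mtry = model$mtry,
               n_trees = model$n_trees, k_embed = model$k_embed,
               seed = model$seed, center = as.list(model$center),
               scale = as.list(model$scale), accuracy = model$accuracy)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  ref <- data.frame(sample = rownames(model$zmat), model$zmat,
                    tsne1 = model$embedding[, 1], tsne2 = model$embedding[, 2],
                    check.names = FALSE)
  write.table(ref, file.path(dir, "reference.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  saveRDS(model$forest, file.path(dir, "forest.rds"))
  invisible(dir)
}

#' Load an origin model saved by [save_origin_model()]
#'
#' @param dir Model directory.
#' @return An `origin_model`.
#' @export
load_origin_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  ref <- read.table(file.path(dir, "reference.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  zmat <- as.matrix(ref[, meta$whitelist, drop = FALSE])
  rownames(zmat) <- ref$sample
  embedding <- as.matrix(ref[, c("tsne1", "tsne2")])
  rownames(embedding) <- ref$sample
  structure(list(
    forest = readRDS(file.path(dir, "forest.rds")),
    whitelist = meta$whitelist,
    center = unlist(meta$center), scale = unlist(meta$scale),
    zmat = zmat, embedding = embedding,
    class_map = unlist(meta$class_map), eliminated = meta$eliminated,
    mtry = meta$mtry, n_trees = meta$n_trees, k_embed = meta$k_embed,
    seed = meta$seed, accuracy = meta$accuracy
  ), class = "origin_model")
}
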