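#' Build the tissue-of-origin feature table
#'
#' Restricts a cytoband SCNA matrix to a whitelist of cancer-associated
#' cytobands, then appends the two pan-genomic covariates the classifier
#' uses: the chromosomal instability number (CIN) score — the sum of the
#' absolute SCNA values over the whitelisted cytobands, with missing values
#' treated as 0 — and a two-dimensional t-SNE embedding of the z-scored
#' whitelisted values.
#'
#' @param x An `scna_matrix` at cytoband level.
#' @param whitelist Character vector of cytoband names; entries absent from
#'   the matrix are reported with a warning and dropped.
#' @param perplexity,n_iter t-SNE parameters, see [run_tsne()].
#' @param seed Seed for the embedding.
#' @return Object of class `feature_table`: list with `features` (numeric
#'   matrix: whitelisted bands + `cin_score` + `tsne1` + `tsne2`), `labels`,
#'   `whitelist` (the retained bands, order fixed), `center`/`scale`
#'   (z-scoring used for the embedding) and `zmat` (the z-scored band
#'   matrix, kept as the embedding reference set).
#' @export
build_features <- function(x, whitelist, perplexity = 30, n_iter = 1000L,
                           seed = 1L) {
  stopifnot(inherits(x, "scna_matrix"))
  whitelist <- as.character(whitelist)
  if (length(whitelist) == 0) stop("empty whitelist", call. = FALSE)
  present <- whitelist %in% colnames(x$values)
  if (!any(present)) {
    stop("whitelist is disjoint from the matrix features", call. = FALSE)
  }
  if (any(!present)) {
    warning("whitelist entries absent from the matrix: ",
            paste(whitelist[!present], collapse = ", "), call. = FALSE)
  }
  wl <- whitelist[present]
  v <- x$values[, wl, drop = FALSE]
  v[is.na(v)] <- 0

  cin <- rowSums(abs(v))

  ctr <- colMeans(v)
  scl <- apply(v, 2, sd)
  scl[scl == 0] <- 1
  z <- scale(v, center = ctr, scale = scl)
  emb <- run_tsne(z, perplexity = perplexity, n_iter = n_iter, seed = seed)

  feats <- cbind(v, cin_score = cin, tsne1 = emb[, 1], tsne2 = emb[, 2])
  structure(list(features = feats, labels = x$labels, whitelist = wl,
                 center = ctr, scale = scl, zmat = z, embedding = emb),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d cytobands (+ CIN + 2 t-SNE)\n",
              nrow(x$features), length(x$whitelist)))
  invisible(x)
}

#' Chromosomal instability number (CIN) score
#'
#' Sum of the absolute SCNA values of a sample over a feature set; missing
#' values contribute 0. Additive over disjoint feature sets.
#'
#' @param values Numeric vector or samples x features matrix.
#' @return Numeric CIN score(s).
#' @export
cin_score <- function(values) {
  if (is.matrix(values)) rowSums(abs(values), na.rm = TRUE)
  else sum(abs(values), na.rm = TRUE)
}

#' Out-of-sample t-SNE coordinates by k-NN barycentric interpolation
#'
#' A new sample's embedding coordinates are the inverse-distance-weighted
#' mean of the coordinates of its `k` nearest training samples in z-scored
#' whitelisted-feature space. A zero-distance match returns that training
#' sample's coordinates exactly. Refitting t-SNE with the new points would
#' both leak and be non-deterministic; interpolation keeps the reference
#' embedding frozen.
#'
#' @param model An `origin_model` (or any list with `zmat`, `embedding`,
#'   `center`, `scale`, `whitelist`, `k_embed`).
#' @param newvalues Numeric matrix of raw (un-scaled) whitelisted cytoband
#'   values, samples in rows, columns in `model$whitelist` order.
#' @param k Number of neighbours (default the model's `k_embed`, itself 15
#'   by default).
#' @return Matrix with columns `tsne1`, `tsne2`.
#' @export
embed_new <- function(model, newvalues, k = NULL) {
  newvalues <- as.matrix(newvalues)
  if (anyNA(newvalues)) stop("samples with missing features cannot be embedded",
                             call. = FALSE)
  if (is.null(k)) k <- if (!is.null(model$k_embed)) model$k_embed else 15L
  k <- min(k, nrow(model$zmat))
  z <- scale(newvalues, center = model$center, scale = model$scale)
  out <- matrix(NA_real_, nrow(z), 2,
                dimnames = list(rownames(newvalues), c("tsne1", "tsne2")))
  for (i in seq_len(nrow(z))) {
    d <- sqrt(colSums((t(model$zmat) - z[i, ])^2))
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    if (any(dn < 1e-12)) {
      hit <- nn[dn < 1e-12]
      out[i, ] <- colMeans(model$embedding[hit, , drop = FALSE])
    } else {
      w <- 1 / dn
      w <- w / sum(w)
      out[i, ] <- colSums(model$embedding[nn, , drop = FALSE] * w)
    }
  }
  out
}

balanced_accuracy <- function(truth, pred) {
  classes <- levels(factor(truth))
  vapply(classes, function(cl) {
    sens <- mean(pred[truth == cl] == cl)
    spec <- mean(pred[truth != cl] != cl)
    (sens + spec) / 2
  }, numeric(1))
}

stratified_split <- function(labels, split, min_per_class) {
  idx_train <- integer(0)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < min_per_class) {
      stop(sprintf(
        "stratification error: class '%s' has %d sample(s), fewer than %d",
        cl, length(members), min_per_class), call. = FALSE)
    }
    ntr <- max(1L, round(split * length(members)))
    if (ntr >= length(members)) ntr <- length(members) - 1L
    idx_train <- c(idx_train, sample(members, ntr))
  }
  sort(idx_train)
}

# Repeated stratified CV over an mtry grid; returns the mtry with the best
# mean fold accuracy.
tune_mtry <- function(xmat, y, grid, folds, repeats, n_trees) {
  acc <- setNames(numeric(length(grid)), as.character(grid))
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(y))
    for (cl in levels(y)) {
      members <- sample(which(y == cl))
      fold_of[members] <- rep_len(seq_len(folds), length(members))
    }
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      for (gi in seq_along(grid)) {
        rf <- randomForest::randomForest(
          x = xmat[tr, , drop = FALSE], y = y[tr],
          ntree = n_trees, mtry = grid[gi]
        )
        pred <- predict(rf, xmat[!tr, , drop = FALSE])
        acc[gi] <- acc[gi] + mean(pred == y[!tr])
      }
    }
  }
  grid[which.max(acc)]
}

#' Train the tumor tissue-of-origin classifier
#'
#' Two-pass random-forest protocol on a cytoband feature table. Pass 1 fits a
#' forest on the raw tumor types (stratified `split` training fraction, mtry
#' tuned by repeated stratified cross-validation on the training split only)
#' and computes per-type balanced accuracy from the out-of-bag predictions;
#' types below `elimination_threshold` are eliminated. Pass 2 maps the
#' surviving types through `class_map` (grouping biologically similar types
#' into classes), refits, and reports overall accuracy and per-class
#' balanced accuracy on the held-out test samples.
#'
#' @param features A `feature_table` from [build_features()].
#' @param labels Raw tumor-type labels (default: the table's own labels).
#' @param n_trees Trees per forest (default 500).
#' @param split Training fraction (default 0.8, stratified by type).
#' @param cv List with `folds` (default 5) and `repeats` (default 3) for the
#'   tuning cross-validation.
#' @param elimination_threshold Per-type balanced-accuracy floor below which
#'   a type is eliminated after pass 1 (default 0.5).
#' @param class_map Named character vector mapping raw types to grouped
#'   classes; defaults to the identity map.
#' @param k_embed Neighbour count for out-of-sample embedding (default 15).
#' @param seed Integer seed; the full procedure is reproducible.
#' @return An object of class `origin_model`: the forest, whitelist,
#'   embedding reference (`zmat`, `embedding`, `center`, `scale`),
#'   `class_map`, `eliminated` types, tuned `mtry`, and an `accuracy` list
#'   (overall test accuracy, per-class balanced accuracy, pass-1 per-type
#'   balanced accuracy, test-set size).
#' @export
train_origin_model <- function(features, labels = NULL, n_trees = 500L,
                               split = 0.8, cv = list(folds = 5L, repeats = 3L),
                               elimination_threshold = 0.5, class_map = NULL,
                               k_embed = 15L, seed = 1L) {
  stopifnot(inherits(features, "feature_table"))
  if (is.null(labels)) labels <- features$labels
  if (is.null(labels)) stop("no labels available", call. = FALSE)
  labels <- as.character(labels)
  xmat <- features$features
  if (length(labels) != nrow(xmat)) stop("label length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("stratification error: need >= 2 classes", call. = FALSE)
  }
  if (is.null(class_map)) {
    class_map <- setNames(unique(labels), unique(labels))
  }

  with_seed(seed, {
    tr_idx <- stratified_split(labels, split, min_per_class = cv$folds)
    te_idx <- setdiff(seq_len(nrow(xmat)), tr_idx)
    ytr <- factor(labels[tr_idx])

    p <- ncol(xmat)
    grid <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 4), floor(p / 2))))
    mtry <- tune_mtry(xmat[tr_idx, , drop = FALSE], ytr, grid,
                      folds = cv$folds, repeats = cv$repeats,
                      n_trees = n_trees)

    # pass 1: raw types, OOB per-type balanced accuracy
    rf1 <- randomForest::randomForest(x = xmat[tr_idx, , drop = FALSE],
                                      y = ytr, ntree = n_trees, mtry = mtry)
    ba1 <- balanced_accuracy(as.character(ytr), as.character(rf1$predicted))
    eliminated <- names(ba1)[ba1 < elimination_threshold]
    retained <- setdiff(unique(labels), eliminated)
    if (length(retained) < 2) {
      stop("fewer than 2 types survive elimination", call. = FALSE)
    }
    missing_map <- setdiff(retained, names(class_map))
    if (length(missing_map) > 0) {
      stop("class_map is not total over retained types: ",
           paste(missing_map, collapse = ", "), call. = FALSE)
    }

    # pass 2: group survivors into classes and refit
    keep_tr <- tr_idx[labels[tr_idx] %in% retained]
    keep_te <- te_idx[labels[te_idx] %in% retained]
    y2 <- factor(class_map[labels[keep_tr]])
    rf2 <- randomForest::randomForest(x = xmat[keep_tr, , drop = FALSE],
                                      y = y2, ntree = n_trees, mtry = mtry)
    pred_te <- predict(rf2, xmat[keep_te, , drop = FALSE])
    truth_te <- class_map[labels[keep_te]]
    overall <- mean(as.character(pred_te) == truth_te)
    ba2 <- balanced_accuracy(truth_te, as.character(pred_te))

    structure(list(
      forest = rf2, whitelist = features$whitelist,
      center = features$center, scale = features$scale,
      zmat = features$zmat, embedding = features$embedding,
      class_map = class_map[retained], eliminated = eliminated,
      mtry = mtry, n_trees = n_trees, k_embed = k_embed, seed = seed,
      accuracy = list(
        overall = overall, per_class_balanced = ba2,
        pass1_per_type_balanced = ba1, n_test = length(keep_te)
      )
    ), class = "origin_model")
  })
}

#' @export
print.origin_model <- function(x, ...) {
  cat(sprintf(
    "origin_model: %d-tree random forest (mtry %d), %d cytobands + CIN + 2 t-SNE\n",
    x$n_trees, x$mtry, length(x$whitelist)))
  cat(sprintf("classes: %s\n", paste(sort(unique(x$class_map)), collapse = ", ")))
  if (length(x$eliminated) > 0) {
    cat(sprintf("eliminated types: %s\n", paste(x$eliminated, collapse = ", ")))
  }
  cat(sprintf("held-out accuracy: %.3f (n = %d)\n",
              x$accuracy$overall, x$accuracy$n_test))
  invisible(x)
}

#' Classify new samples with a trained tissue-of-origin model
#'
#' Builds the model's feature set for each new sample — whitelisted cytoband
#' values (missing cytobands imputed as 0 with a warning), CIN score and
#' interpolated t-SNE coordinates — and returns the forest's predicted class
#' with per-class vote fractions (summing to 1). Refuses to classify when
#' fewer than 80% of the model's cytobands are present.
#'
#' @param model An `origin_model`.
#' @param x An `scna_matrix` at cytoband level (or a plain samples x
#'   cytobands matrix).
#' @param patients Optional per-sample patient ids for the per-patient
#'   summary.
#' @param target_class Optional designated class; with `patients`, the
#'   summary reports for each patient whether at least one of their samples
#'   was assigned it.
#' @return List of class `origin_prediction` with `predictions` (data frame:
#'   sample, predicted, vote fraction columns) and, when requested,
#'   `patient_summary`.
#' @export
classify_samples <- function(model, x, patients = NULL, target_class = NULL) {
  stopifnot(inherits(model, "origin_model"))
  values <- if (inherits(x, "scna_matrix")) x$values else as.matrix(x)
  present <- model$whitelist %in% colnames(values)
  coverage <- mean(present)
  if (coverage < 0.8) {
    stop(sprintf(
      "refusing to classify: only %.0f%% of the model's %d cytobands are present (>= 80%% required)",
      100 * coverage, length(model$whitelist)), call. = FALSE)
  }
  if (any(!present)) {
    warning(sprintf("%d model cytoband(s) missing; imputed as 0",
                    sum(!present)), call. = FALSE)
  }
  v <- matrix(0, nrow(values), length(model$whitelist),
              dimnames = list(rownames(values), model$whitelist))
  v[, model$whitelist[present]] <- values[, model$whitelist[present], drop = FALSE]
  v[is.na(v)] <- 0

  emb <- embed_new(model, v)
  feats <- cbind(v, cin_score = cin_score(v), tsne1 = emb[, 1],
                 tsne2 = emb[, 2])
  votes <- predict(model$forest, feats, type = "prob")
  votes <- votes / rowSums(votes)
  predicted <- colnames(votes)[max.col(votes, ties.method = "first")]

  preds <- data.frame(
    sample = if (!is.null(rownames(values))) rownames(values)
             else paste0("S", seq_len(nrow(values))),
    predicted = predicted, stringsAsFactors = FALSE
  )
  preds <- cbind(preds, as.data.frame(votes))

  patient_summary <- NULL
  if (!is.null(patients) && !is.null(target_class)) {
    hit <- tapply(predicted == target_class, patients, any)
    patient_summary <- data.frame(
      patient = names(hit), any_target_class = as.logical(hit),
      stringsAsFactors = FALSE
    )
  }
  structure(list(predictions = preds, patient_summary = patient_summary,
                 coverage = coverage),
            class = "origin_prediction")
}

#' @export
print.origin_prediction <- function(x, ...) {
  tab <- table(x$predictions$predicted)
  cat(sprintf("origin_prediction: %d sample(s)\n", nrow(x$predictions)))
  print(tab)
  if (!is.null(x$patient_summary)) {
    cat(sprintf("patients with >= 1 sample at the designated class: %d / %d\n",
                sum(x$patient_summary$any_target_class),
                nrow(x$patient_summary)))
  }
  invisible(x)
}

#' @export
predict.origin_model <- function(object, newdata, ...) {
  classify_samples(object, newdata, ...)
}
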