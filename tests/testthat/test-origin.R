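# Shared separable cohort for the classifier tests (built once; training the
# forest dominates the cost, so the fixtures are kept lean).
origin_fixture <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      bands <- sprintf("%dq%d", rep(1:6, each = 8), 1:8)
      sigs <- random_signature_set(bands, paste0("class", 1:5),
                                   events_per_class = 6, prevalence = 1,
                                   amplitude = 1, seed = 3)
      coh <- simulate_cohort(sigs, 60, passenger_rate = 1, noise_sd = 0.05,
                             seed = 4)
      ft <- build_features(coh, whitelist = bands, seed = 5)
      model <- train_origin_model(ft, n_trees = 300,
                                  cv = list(folds = 3L, repeats = 1L),
                                  seed = 6)
      env <<- list(bands = bands, sigs = sigs, cohort = coh, ft = ft,
                   model = model)
    }
    env
  }
})

test_that("CIN is the sum of absolute SCNA values, missing as zero", {
  expect_equal(cin_score(c(0.5, -0.5, 1)), 2)
  expect_equal(cin_score(c(0, 0, 0)), 0)
  expect_equal(cin_score(c(1, NA, -2)), 3)
  m <- matrix(c(1, -1, 0.5, NA), 2)
  expect_equal(cin_score(m), c(1.5, 1))
  # additivity over disjoint whitelists
  set.seed(9)
  v <- rnorm(20)
  expect_equal(cin_score(v[1:8]) + cin_score(v[9:20]), cin_score(v))
})

test_that("build_features validates the whitelist and attaches covariates", {
  fx <- origin_fixture()
  expect_error(build_features(fx$cohort, character(0)), "empty")
  expect_error(build_features(fx$cohort, c("zz1", "zz2")), "disjoint")
  expect_warning(ft <- build_features(fx$cohort, c(fx$bands[1:10], "zz"),
                                      n_iter = 50, seed = 1), "zz")
  expect_equal(ncol(ft$features), 13L)  # 10 bands + CIN + 2 embedding
  expect_true(all(is.finite(ft$features[, c("tsne1", "tsne2")])))
  expect_equal(unname(ft$features[, "cin_score"]),
               unname(rowSums(abs(fx$cohort$values[, fx$bands[1:10]]))))
})

test_that("duplicated samples embed next to each other relative to class spread", {
  set.seed(10)
  x <- rbind(matrix(rnorm(30 * 10, 0, 0.3), 30),
             matrix(rnorm(30 * 10, 4, 0.3), 30))
  x[31, ] <- x[1, ]  # duplicate a class-1 sample inside class 2's block
  y <- run_tsne(x, perplexity = 10, n_iter = 1000, seed = 2)
  d_dup <- sqrt(sum((y[1, ] - y[31, ])^2))
  between <- sqrt(sum((colMeans(y[1:30, ]) - colMeans(y[32:60, ]))^2))
  expect_lt(d_dup, 0.05 * between)
  # and the duplicate is its twin's nearest neighbour in the embedding
  expect_equal(which.min(as.matrix(dist(y))[1, -1]), 30L, ignore_attr = TRUE)
})

test_that("out-of-sample embedding interpolates its nearest neighbours", {
  fx <- origin_fixture()
  m <- fx$model
  # a training sample lands exactly on its own coordinates
  raw <- sweep(sweep(m$zmat[7, , drop = FALSE], 2, m$scale, "*"),
               2, m$center, "+")
  expect_equal(unname(embed_new(m, raw)[1, ]), unname(m$embedding[7, ]))
  # a point equidistant from two references maps to their midpoint (k = 2)
  toy <- list(zmat = rbind(c(-1, 0), c(1, 0)),
              embedding = rbind(c(0, 0), c(4, 2)),
              center = c(0, 0), scale = c(1, 1), k_embed = 2L,
              whitelist = c("a", "b"))
  expect_equal(unname(embed_new(toy, matrix(c(0, 5), 1), k = 2)[1, ]),
               c(2, 1))
  expect_error(embed_new(m, matrix(NA_real_, 1, length(m$whitelist))),
               "missing")
})

test_that("held-out samples land nearest their own class centroid", {
  fx <- origin_fixture()
  holdout <- simulate_cohort(fx$sigs, 6, passenger_rate = 1, noise_sd = 0.05,
                             seed = 44)
  emb <- embed_new(fx$model, holdout$values[, fx$model$whitelist])
  centroids <- apply(fx$model$embedding, 2, tapply,
                     fx$cohort$labels, mean)
  nearest <- apply(emb, 1, function(p) {
    rownames(centroids)[which.min(colSums((t(centroids) - p)^2))]
  })
  expect_gte(mean(nearest == holdout$labels), 0.9)
})

test_that("training is seeded-deterministic and validates stratification", {
  fx <- origin_fixture()
  m2 <- train_origin_model(fx$ft, n_trees = 300,
                           cv = list(folds = 3L, repeats = 1L), seed = 6)
  expect_identical(fx$model$accuracy, m2$accuracy)
  expect_identical(predict(fx$model$forest, fx$ft$features),
                   predict(m2$forest, fx$ft$features))
  # single class -> stratification error
  one <- fx$ft
  expect_error(train_origin_model(one, labels = rep("only", nrow(one$features)),
                                  cv = list(folds = 3L, repeats = 1L)),
               "2 classes")
  # a class smaller than the fold count -> stratification error
  labs <- fx$cohort$labels
  labs[labs == "class5"] <- "class4"
  labs[1:2] <- "tiny"
  expect_error(train_origin_model(fx$ft, labels = labs,
                                  cv = list(folds = 3L, repeats = 1L)),
               "stratification")
})

test_that("classification returns normalized votes and respects coverage", {
  fx <- origin_fixture()
  qc <- simulate_cohort(fx$sigs, 4, passenger_rate = 1, noise_sd = 0.05,
                        seed = 45)
  pred <- classify_samples(fx$model, qc)
  votes <- as.matrix(pred$predictions[, -(1:2)])
  expect_equal(unname(rowSums(votes)), rep(1, nrow(votes)))
  expect_gte(mean(pred$predictions$predicted == qc$labels), 0.9)
  # resubstitution accuracy is at least the held-out accuracy
  resub <- classify_samples(fx$model, fx$cohort)
  expect_gte(mean(resub$predictions$predicted == fx$cohort$labels),
             fx$model$accuracy$overall - 1e-9)
  # an all-zero profile matches no signature: votes spread over classes
  flat <- matrix(0, 1, length(fx$bands), dimnames = list("flat", fx$bands))
  pf <- classify_samples(fx$model, flat)
  expect_lt(max(as.matrix(pf$predictions[, -(1:2)])), 0.6)
  # per-patient summary
  pp <- classify_samples(fx$model, qc, patients = rep(c("A", "B"), 10),
                         target_class = "class1")
  expect_equal(nrow(pp$patient_summary), 2L)
  # insufficient cytoband coverage -> refusal
  few <- qc$values[, 1:10]
  expect_error(classify_samples(fx$model, few), "80%")
})

test_that("model bundles survive a save/load round trip", {
  fx <- origin_fixture()
  dir <- tempfile("model")
  save_origin_model(fx$model, dir)
  m2 <- load_origin_model(dir)
  qc <- simulate_cohort(fx$sigs, 3, noise_sd = 0.05, seed = 46)
  p1 <- classify_samples(fx$model, qc)
  p2 <- classify_samples(m2, qc)
  expect_equal(p1$predictions, p2$predictions)
})

test_that("test accuracy degrades monotonically with cohort noise", {
  bands <- sprintf("%dq%d", rep(1:6, each = 8), 1:8)
  sigs <- random_signature_set(bands, paste0("class", 1:4),
                               events_per_class = 6, prevalence = 1,
                               amplitude = 1, seed = 13)
  acc <- vapply(c(0.05, 0.2, 0.5, 1.0), function(noise) {
    mean(vapply(1:8, function(s) {
      coh <- simulate_cohort(sigs, 40, passenger_rate = 1, noise_sd = noise,
                             seed = 100 * s)
      ft <- build_features(coh, bands, n_iter = 400, seed = s)
      m <- train_origin_model(ft, n_trees = 200,
                              cv = list(folds = 3L, repeats = 1L), seed = s)
      m$accuracy$overall
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.01))
})
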