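test_that("subset fitness honours its conventions", {
  syn <- generate_feature_table(90, d_informative = 3, d_noise = 4,
                                effect_size = 4, n_classes = 3, seed = 5)
  d <- ncol(syn$x)
  expect_equal(subset_fitness(syn$x, syn$y, rep(0L, d)), 0)

  mask <- rep(0L, d); mask[syn$informative] <- 1L
  f <- subset_fitness(syn$x, syn$y, mask, seed = 2)
  expect_identical(f, subset_fitness(syn$x, syn$y, mask, seed = 2))
  expect_true(f > 0.8)   # informative columns separate the classes

  expect_error(subset_fitness(syn$x, syn$y, mask[-1]), "mask length")
})

test_that("subset fitness agrees with an explicit per-fold fknn route", {
  syn <- generate_feature_table(120, d_informative = 3, d_noise = 5,
                                effect_size = 1.5, n_classes = 3, seed = 9)
  x <- as.matrix(syn$x); y <- syn$y
  mask <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  folds <- stratified_kfold(y, r = 5, seed = 4)
  xm <- x[, mask == 1L, drop = FALSE]
  f1s <- vapply(folds, function(test) {
    fit <- fknn(xm[-test, , drop = FALSE], y[-test], k = 4, m = 2)
    pred <- predict(fit, xm[test, , drop = FALSE])
    unname(precision_recall_f1(y[test], pred, levels = levels(y))$macro["f1"])
  }, numeric(1))
  expect_equal(subset_fitness(x, y, mask, k = 4, m = 2, folds = 5, seed = 4),
               mean(f1s), tolerance = 1e-12)
})

test_that("a clearly separable table reaches perfect fitness", {
  syn <- generate_feature_table(60, d_informative = 2, d_noise = 0,
                                effect_size = 8, n_classes = 2, seed = 11)
  expect_equal(subset_fitness(syn$x, syn$y, c(1L, 1L), seed = 1), 1.0)
})

test_that("the wrapper recovers planted columns and beats all-features", {
  syn <- generate_feature_table(200, d_informative = 3, d_noise = 9,
                                effect_size = 3, n_classes = 3, seed = 31)
  fit <- qfuzzy(syn$x, syn$y,
                control = swarm_control(S = 12, T = 20, seed = 8))
  expect_s3_class(fit, "qfuzzy")
  expect_length(fit$mask, 12)
  expect_gte(fit$n_selected, 1)
  # no stale caching: the reported fitness re-derives from the mask
  expect_equal(fit$fitness,
               subset_fitness(syn$x, syn$y, fit$mask, k = fit$k, m = fit$m,
                              folds = fit$folds, seed = fit$fold_seed))
  # most planted columns are kept
  expect_gte(sum(fit$mask[syn$informative]), 2)
  # selection does not fall below the all-features reference on this table
  base <- all_features_baseline(syn$x, syn$y, seed = fit$fold_seed)
  expect_gte(fit$fitness, base$fitness)
})

test_that("both optimizer back-ends expose identical result structure", {
  syn <- generate_feature_table(90, d_informative = 2, d_noise = 4,
                                effect_size = 4, n_classes = 3, seed = 13)
  for (opt in c("qpso", "pso")) {
    fit <- qfuzzy(syn$x, syn$y, optimizer = opt,
                  control = swarm_control(S = 8, T = 8, seed = 3))
    expect_identical(fit$optimizer, opt)
    expect_true(all(diff(fit$trace) >= 0))
    expect_true(fit$fitness >= 0 && fit$fitness <= 1)
    expect_named(fit$evaluation$macro, c("precision", "recall", "f1"))
    expect_true(is.finite(fit$evaluation$kappa))
  }
})

test_that("fit methods print, summarise, predict and plot", {
  syn <- generate_feature_table(90, d_informative = 2, d_noise = 3,
                                effect_size = 4, n_classes = 3, seed = 17)
  fit <- qfuzzy(syn$x, syn$y, control = swarm_control(S = 8, T = 6, seed = 2))
  expect_output(print(fit), "feature entries selected")
  expect_output(print(summary(fit)), "Pooled-fold evaluation")
  expect_identical(coef(fit), fit$mask)
  pred <- predict(fit, syn$x)
  expect_s3_class(pred, "factor")
  expect_length(pred, nrow(syn$x))
  expect_gt(mean(pred == syn$y), 0.8)
  memb <- predict(fit, syn$x, type = "membership")
  expect_equal(rowSums(memb), rep(1, nrow(syn$x)), tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_error(predict(fit, syn$x[, 1, drop = FALSE]), "lacks")
})

test_that("the formula interface matches the default method", {
  syn <- generate_feature_table(90, d_informative = 2, d_noise = 3,
                                effect_size = 4, n_classes = 3, seed = 23)
  df <- cbind(class = syn$y, syn$x)
  f1 <- qfuzzy(class ~ ., data = df,
               control = swarm_control(S = 6, T = 5, seed = 4))
  f2 <- qfuzzy(syn$x, syn$y, control = swarm_control(S = 6, T = 5, seed = 4))
  expect_identical(f1$mask, f2$mask)
  expect_equal(f1$fitness, f2$fitness)
})

test_that("pure-noise columns do not raise all-features fitness on average", {
  seeds <- 1:50
  delta <- vapply(seeds, function(s) {
    syn <- generate_feature_table(80, d_informative = 3, d_noise = 0,
                                  effect_size = 2, n_classes = 2, seed = s)
    set.seed(s + 1000)
    with_noise <- cbind(as.matrix(syn$x),
                        matrix(rnorm(80 * 6), 80, 6))
    f_clean <- subset_fitness(syn$x, syn$y, rep(1L, 3), seed = s)
    f_noisy <- subset_fitness(with_noise, syn$y, rep(1L, 9), seed = s)
    f_noisy - f_clean
  }, numeric(1))
  # one-sided: adding noise must not help on average
  expect_lte(mean(delta), 0)
  expect_lt(t.test(delta, alternative = "less")$p.value, 0.05)
})

test_that("selection results serialize to JSON with provenance", {
  syn <- generate_feature_table(60, d_informative = 2, d_noise = 2,
                                effect_size = 4, n_classes = 2, seed = 3)
  fit <- qfuzzy(syn$x, syn$y, control = swarm_control(S = 6, T = 4, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  qfuzzy_to_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$config$seed, 9)
  expect_equal(back$fitness, fit$fitness)
  expect_equal(sum(back$mask), fit$n_selected)
  expect_true(nzchar(back$package_version))
})
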