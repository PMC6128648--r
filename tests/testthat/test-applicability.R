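# Ensemble-variance applicability domain.

# Heterogeneous training set (dense core + sparse wide tail) with a fitted
# model and CV, shared across tests.
ad_context <- function() {
  cached("ad_context", {
    core <- simulate_dataset(effect_spec(c(x1 = 3, x2 = 2), noise_sd = 2,
                                         n = 360, n_noise = 3, seed = 101))
    tail <- simulate_dataset(effect_spec(c(x1 = 3, x2 = 2), noise_sd = 2,
                                         n = 40, n_noise = 3, seed = 102),
                             scale = 3)
    train <- combine_datasets(core, tail)
    cv <- cross_validate(train, forest_params(seed = 1), rounds = 4,
                         folds = 5, seed = 201)
    model <- train_forest(train, forest_params(seed = 301))
    list(train = train, cv = cv, model = model,
         reference = cv_reference_variance(cv))
  })
}

test_that("ensemble variance follows the population convention", {
  ## hand-built per-tree matrix via a 2-tree surrogate: use the formula on
  ## a degenerate forest instead -- all trees agree => variance 0
  dm <- signal_dm()
  const <- thermoforest:::new_descriptor_matrix(
    dm$x, dm$mutants, rep(2, nrow(dm$x)))
  m <- suppressWarnings(train_forest(const, forest_params(seed = 1)))
  v <- ensemble_variance(m, dm$x[1:5, ])
  expect_equal(v, rep(0, 5))

  ## population variance of per-tree values [1, 3] is 1.0
  fake <- list(per_tree = matrix(c(1, 3), 1, 2))
  expect_equal(rowMeans(fake$per_tree^2) - rowMeans(fake$per_tree)^2, 1)
})

test_that("per-mutant CV reference matches its closed form", {
  ctx <- ad_context()
  cv <- ctx$cv
  ## identical predictions across rounds => per-mutant reference 0
  cv0 <- cv
  cv0$predictions <- matrix(1.5, nrow(cv$predictions), ncol(cv$predictions))
  expect_equal(cv_reference_variance(cv0, method = "per_mutant"), 0)
  ## predictions alternating {0, 2} per mutant => population variance 1
  cv1 <- cv
  cv1$predictions <- matrix(c(0, 2, 0, 2), nrow(cv$predictions), 4,
                            byrow = TRUE)
  expect_equal(cv_reference_variance(cv1, method = "per_mutant"), 1)
  expect_equal(cv_reference_variance(cv1, method = "per_mutant",
                                     aggregate = "median"), 1)
  ## residual reference equals the pooled error variance
  err <- as.vector(cv$predictions) - rep(cv$observed, ncol(cv$predictions))
  expect_equal(cv_reference_variance(cv), mean(err^2) - mean(err)^2)
  expect_error(cv_reference_variance(structure(list(
    predictions = cv$predictions[, 1, drop = FALSE], observed = cv$observed),
    class = "cv_result")), "2 cross-validation rounds")
})

test_that("extreme references give all-in or all-out verdicts", {
  ctx <- ad_context()
  q <- ctx$train$x[1:50, ]
  rep_big <- ad_assess(ctx$model, q, 1e9)
  expect_equal(attr(rep_big, "fraction_out_of_domain"), 0)
  rep_zero <- ad_assess(ctx$model, q, 0)
  expect_equal(attr(rep_zero, "fraction_out_of_domain"), 100)
  expect_error(ad_assess(ctx$model, q, Inf), "is.finite")
})

test_that("fraction out of domain is monotone in the reference threshold", {
  ctx <- ad_context()
  q <- ctx$train$x[1:100, ]
  refs <- c(0, 0.5, 2, 8, 32, 1e6)
  fr <- vapply(refs, function(r) {
    attr(ad_assess(ctx$model, q, r), "fraction_out_of_domain")
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("far-out queries have larger ensemble variance than in-range ones", {
  ctx <- ad_context()
  qin <- simulate_dataset(effect_spec(c(x1 = 3, x2 = 2), noise_sd = 2,
                                      n = 100, n_noise = 3, seed = 401))
  qfar <- simulate_dataset(effect_spec(c(x1 = 3, x2 = 2), noise_sd = 2,
                                       n = 100, n_noise = 3, seed = 402),
                           shift = 6)
  vin <- ensemble_variance(ctx$model, qin$x)
  vfar <- ensemble_variance(ctx$model, qfar$x)
  expect_gt(median(vfar), median(vin))
})

test_that("distribution-shifted queries fall out of domain more often", {
  ctx <- ad_context()
  qin <- simulate_dataset(effect_spec(c(x1 = 3, x2 = 2), noise_sd = 2,
                                      n = 150, n_noise = 3, seed = 403))
  qsh <- simulate_dataset(effect_spec(c(x1 = 3, x2 = 2), noise_sd = 2,
                                      n = 150, n_noise = 3, seed = 404),
                          shift = 4)
  f_in <- attr(ad_assess(ctx$model, qin$x, ctx$reference),
               "fraction_out_of_domain")
  f_sh <- attr(ad_assess(ctx$model, qsh$x, ctx$reference),
               "fraction_out_of_domain")
  expect_gt(f_sh, f_in)
  ## and the in-distribution fraction is not saturated
  expect_lt(f_in, 100)
})
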