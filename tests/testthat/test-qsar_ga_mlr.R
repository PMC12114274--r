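noiseless_fm <- function(seed = 1, n = 30, p = 10, subset = c(2, 5),
                         betas = c(40, -25), intercept = 50) {
  synth_feature_table(planted_model_spec(
    n_rows = n, p_variables = p, true_subset = subset, betas = betas,
    intercept = intercept, noise_sd = 0, missing_rate = 0, seed = seed))
}

test_that("OLS reproduces exact linear structure and degenerate cases", {
  ft <- noiseless_fm()
  fit <- fit_mlr(ft$matrix, c("V2", "V5"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), c(40, -25), tolerance = 1e-8)
  expect_equal(fit$intercept, 50, tolerance = 1e-7)
  expect_equal(unname(fit$predictions), ft$matrix$response, tolerance = 1e-9)

  # constant response: R^2 = 0 by convention
  fm0 <- ft$matrix
  fm0$response <- rep(42, length(fm0$response))
  expect_equal(fit_mlr(fm0, 1:2)$r_squared, 0)

  # variables addressable by rendered residue label too
  lab <- ft$matrix$catalog$label[c(2, 5)]
  expect_equal(fit_mlr(ft$matrix, lab)$r_squared, 1, tolerance = 1e-12)
})

test_that("fit_mlr agrees with the normal-equations hand solver", {
  for (seed in 1:5) {
    ft <- synth_feature_table(planted_model_spec(
      n_rows = 35, p_variables = 12, k = 4, noise_sd = 5, seed = 300 + seed))
    idx <- withr::with_seed(seed, sort(sample.int(12, 5)))
    fit <- fit_mlr(ft$matrix, idx)
    want <- oracle_ols(ft$matrix$values[, idx, drop = FALSE],
                       ft$matrix$response)
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(want$beta), tolerance = 1e-8)
    expect_equal(fit$r_squared, want$r2, tolerance = 1e-8)
    expect_equal(fit$rmse, want$rmse, tolerance = 1e-8)
  }
})

test_that("rank deficiency and short designs are rejected by name", {
  ft <- noiseless_fm(seed = 2)
  fm <- ft$matrix
  fm$values[, 3] <- fm$values[, 2]   # exact collinearity
  expect_error(fit_mlr(fm, c(2, 3, 7)), "collinear.*V[23]")
  small <- synth_feature_table(planted_model_spec(
    n_rows = 4, p_variables = 6, k = 2, noise_sd = 0, missing_rate = 0,
    seed = 3))
  expect_error(fit_mlr(small$matrix, 1:3), "at least")
  expect_error(fit_mlr(ft$matrix, c(1, 99)), "out of range|unknown")
})

test_that("adding a variable never decreases in-fit R^2", {
  for (seed in 1:4) {
    ft <- synth_feature_table(planted_model_spec(
      n_rows = 40, p_variables = 15, k = 3, noise_sd = 10, seed = 400 + seed))
    idx <- withr::with_seed(seed, sample.int(15, 8))
    r2 <- vapply(2:8, function(m) fit_mlr(ft$matrix, idx[1:m])$r_squared,
                 numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("exhaustive search finds planted subsets", {
  # p = 3, k = 1, response exactly 2 * V2
  ft <- synth_feature_table(planted_model_spec(
    n_rows = 20, p_variables = 3, true_subset = 2, betas = 2, intercept = 0,
    noise_sd = 0, missing_rate = 0, seed = 5))
  sel <- exhaustive_select(ft$matrix, 1)
  expect_identical(sel$variables, "V2")
  expect_equal(sel$fitness, 1, tolerance = 1e-12)

  # p = 10, k = 3, mild noise
  ft2 <- synth_feature_table(planted_model_spec(
    n_rows = 40, p_variables = 10, true_subset = c(2, 6, 9),
    betas = c(30, -30, 30), noise_sd = 0.5, missing_rate = 0, seed = 6))
  sel2 <- exhaustive_select(ft2$matrix, 3)
  expect_identical(sel2$variable_indices, c(2L, 6L, 9L))

  # k = p: fitness equals the full-model R^2
  sel_full <- exhaustive_select(ft2$matrix, 10)
  expect_equal(sel_full$fitness, fit_mlr(ft2$matrix, 1:10)$r_squared,
               tolerance = 1e-12)

  expect_error(exhaustive_select(ft2$matrix, 5, max_combinations = 10),
               "ga_select")
})

test_that("the GA is elitist, seeded-reproducible, and beats random subsets", {
  ft <- synth_feature_table(planted_model_spec(
    n_rows = 40, p_variables = 20, k = 4, noise_sd = 2, seed = 7))
  cfg <- ga_config(k = 4, population_size = 40, generations = 60, seed = 99)
  sel <- ga_select(ft$matrix, cfg)
  expect_true(all(diff(sel$trace) >= 0))          # elitism
  expect_equal(sel$fitness, sel$fit$r_squared)
  expect_length(sel$variable_indices, 4)

  sel_again <- ga_select(ft$matrix, cfg)           # bit-reproducible
  expect_identical(sel$variable_indices, sel_again$variable_indices)
  expect_identical(sel$trace, sel_again$trace)

  rand_fit <- withr::with_seed(1, vapply(1:100, function(i) {
    fit_mlr(ft$matrix, sort(sample.int(20, 4)))$r_squared
  }, numeric(1)))
  expect_gte(sel$fitness, stats::median(rand_fit))

  expect_error(ga_select(ft$matrix, ga_config(k = 25)), "exceeds")
})

test_that("the GA matches the exhaustive oracle on small instances", {
  for (seed in 1:5) {
    ft <- synth_feature_table(planted_model_spec(
      n_rows = 40, p_variables = 12, k = 3, noise_sd = 2, seed = 500 + seed))
    ex <- exhaustive_select(ft$matrix, 3)
    ga <- ga_select(ft$matrix, ga_config(k = 3, population_size = 50,
                                         generations = 80, seed = seed))
    expect_equal(ga$fitness, ex$fitness, tolerance = 1e-12)
    expect_identical(ga$variable_indices, ex$variable_indices)
  }
})

test_that("sign report maps coefficients to interpretation tags", {
  ft <- noiseless_fm(seed = 8, subset = c(1, 4), betas = c(-12, 30))
  fit <- fit_mlr(ft$matrix, c(1, 4))
  rep <- sign_report(fit)
  expect_s3_class(rep, "SignReport")
  expect_identical(rep$sign, c("-", "+"))
  expect_identical(rep$interpretation,
                   c("short-bond-favors-activity",
                     "no-interaction-favors-activity"))
  expect_identical(rep$label, ft$matrix$catalog$label[c(1, 4)])
  # bridged variables render with the W prefix
  expect_identical(rep$label[ft$matrix$catalog$bridged[c(1, 4)]],
                   paste0("W", ft$matrix$catalog$residue_key[c(1, 4)])[
                     ft$matrix$catalog$bridged[c(1, 4)]])
  # an exactly-zero coefficient maps to sign "0", tag none
  fit$coefficients[1] <- 0
  rep0 <- sign_report(fit)
  expect_identical(rep0$sign[1], "0")
  expect_identical(rep0$interpretation[1], "none")
})
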