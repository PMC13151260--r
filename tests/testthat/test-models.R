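test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  y <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  x <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  f <- fit_logistic(list(matrix = cbind(exposure = x), outcome = y))
  expect_equal(f$table$or[f$table$term == "exposure"], 9, tolerance = 1e-6)
  expect_true(f$converged)
  expect_false(f$separation)
  # CI brackets the estimate and p is small
  row <- f$table[f$table$term == "exposure", ]
  expect_true(row$ci_low <= row$or && row$or <= row$ci_high)
  expect_lt(row$p, 0.05)
  expect_true(row$significant)
})

test_that("2x2 odds ratios match ad/bc across random tables", {
  set.seed(13)
  for (i in 1:10) {
    tab <- matrix(sample(5:50, 4), 2)
    y <- rep(c(1, 1, 0, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    x <- rep(c(1, 0, 1, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    f <- fit_logistic(list(matrix = cbind(x = x), outcome = y))
    expect_equal(f$table$or[2],
                 (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
                 tolerance = 1e-6)
  }
})

test_that("separation is flagged and an empty class is an error", {
  y <- rep(0:1, each = 20)
  expect_warning(f <- fit_logistic(list(matrix = cbind(x = y), outcome = y)),
                 "separation")
  expect_true(f$separation)
  expect_error(fit_logistic(list(matrix = cbind(x = y), outcome = rep(1, 40))),
               "single class")
})

test_that("full shrinkage zeroes every coefficient", {
  d <- toy_design(300, seed = 2)
  f <- fit_lasso_logistic(d, force_lambda = Inf, n_boot_ci = 0)
  ors <- f$table$or[f$table$term != "(Intercept)"]
  expect_true(all(ors == 1))
})

test_that("the unpenalized limit matches the logistic fit on the standardized design", {
  d <- toy_design(400, seed = 3)
  f0 <- fit_lasso_logistic(d, force_lambda = 0, n_boot_ci = 0)
  fg <- fit_logistic(list(matrix = scale(d$matrix), outcome = d$outcome))
  expect_equal(f0$table$estimate, fg$table$estimate, tolerance = 1e-4)
})

test_that("the active set shrinks as the penalty grows", {
  d <- toy_design(500, seed = 4, p_noise = 4)
  f <- fit_lasso_logistic(d, seed = 4, n_boot_ci = 0)
  lams <- f$lambda_grid[seq(1, 100, by = 12)]
  nonzero <- vapply(lams, function(l) {
    ff <- fit_lasso_logistic(d, force_lambda = l, n_boot_ci = 0)
    sum(ff$table$estimate[ff$table$term != "(Intercept)"] != 0)
  }, numeric(1))
  # lams descend, so the active set may only grow along the sequence
  expect_true(all(diff(nonzero) >= 0))
})

test_that("cross-validated selection keeps planted signals and is reproducible", {
  set.seed(6)
  n <- 2000
  X <- cbind(s1 = rbinom(n, 1, .5), s2 = rbinom(n, 1, .5),
             z1 = rbinom(n, 1, .5), z2 = rbinom(n, 1, .5))
  y <- rbinom(n, 1, plogis(-0.5 + 1.6 * X[, "s1"] - 1.2 * X[, "s2"]))
  d <- list(matrix = X, outcome = y)
  f <- fit_lasso_logistic(d, seed = 11, n_boot_ci = 40)
  b <- f$table[f$table$term != "(Intercept)", ]
  expect_true(all(b$estimate[b$term %in% c("s1", "s2")] != 0))
  expect_true(f$lambda_star %in% f$lambda_grid)
  f2 <- fit_lasso_logistic(d, seed = 11, n_boot_ci = 40)
  expect_equal(f$table, f2$table)
  # bootstrap intervals exist for nonzero terms
  expect_false(anyNA(b[b$term == "s1", c("ci_low", "ci_high")]))
})

test_that("forest tables follow the reporting conventions", {
  d <- toy_design(300, seed = 7)
  f <- fit_logistic(d)
  ft <- forest_table(f)
  expect_equal(names(ft), c("term", "or", "ci_low", "ci_high", "p"))
  expect_false("(Intercept)" %in% ft$term)

  fl <- fit_lasso_logistic(d, force_lambda = Inf, n_boot_ci = 0)
  ftl <- forest_table(fl)
  expect_true(all(ftl$or == 1))
  expect_true(all(is.na(ftl$ci_low)))

  empty <- structure(list(table = data.frame(
    term = "(Intercept)", estimate = 0.1, or = exp(0.1),
    ci_low = NA_real_, ci_high = NA_real_)), class = "model_fit")
  expect_equal(nrow(forest_table(empty)), 0)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_forest(f, tmp)
  expect_length(jsonlite::read_json(tmp), nrow(ft))
})

test_that("Wald intervals have near-nominal coverage (quick check)", {
  cover <- 0
  for (s in 1:40) {
    set.seed(derive_seed(s, "cov-quick"))
    x <- rbinom(400, 1, 0.5)
    y <- rbinom(400, 1, plogis(-0.5 + log(3) * x))
    f <- suppressWarnings(fit_logistic(list(matrix = cbind(x = x), outcome = y)))
    ci <- f$table[f$table$term == "x", ]
    cover <- cover + (ci$ci_low <= 3 && 3 <= ci$ci_high)
  }
  expect_gte(cover / 40, 0.80)
})
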