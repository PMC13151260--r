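#' Maximum-likelihood logistic regression with Wald odds-ratio intervals
#'
#' Fits the binary walking outcome on the selected coded variables by
#' iteratively reweighted least squares (tight convergence: relative
#' deviance change below 1e-10, at most 100 iterations). Reports, per term,
#' the log-odds coefficient, its Wald standard error from the observed
#' information, OR = exp(coef), the 95% interval exp(coef +/- 1.96 SE), and
#' the two-sided Wald p-value. The study's significance threshold (p <
#' 0.05) is flagged in the `significant` column.
#'
#' Complete or quasi-complete separation is detected heuristically as a
#' coefficient exceeding 15 in absolute value; the fit is returned with a
#' warning and `separation = TRUE`.
#'
#' @param design a `binary_design` from [code_design()], or any list with a
#'   0/1 `matrix` and 0/1 `outcome`.
#' @param terms columns of the design matrix to include; defaults to all.
#' @return object of class `model_fit`: list with `table` (term, estimate,
#'   se, or, ci_low, ci_high, p, significant), `converged`, `separation`,
#'   `n`.
#' @export
fit_logistic <- function(design, terms = colnames(design$matrix)) {
  X <- design$matrix
  y <- design$outcome
  missing_terms <- setdiff(terms, colnames(X))
  if (length(missing_terms))
    stop("terms not in design: ", paste(missing_terms, collapse = ", "))
  if (length(unique(y)) < 2) stop("outcome has a single class")

  df <- data.frame(.y = y, X[, terms, drop = FALSE], check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", terms), response = ".y")
  fit <- suppressWarnings(stats::glm(
    fml, family = stats::binomial(), data = df,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))

  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  tab <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est - 1.96 * se)),
    ci_high = exp(unname(est + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE)
  tab$term <- gsub("`", "", tab$term)
  tab$significant <- tab$p < 0.05
  separation <- any(abs(est[-1]) > 15)
  if (separation)
    warning("possible separation: a coefficient exceeds 15 in absolute value")
  structure(list(table = tab, converged = fit$converged,
                 separation = separation, n = nrow(df)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> logistic regression, n = ", x$n,
      if (x$separation) " [separation flagged]", "\n", sep = "")
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

# stratified fold assignment: classes split separately, seeded
.stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds)
      stop("a class has fewer members than folds; cannot stratify")
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' L1-penalized logistic regression with cross-validated penalty
#'
#' Columns are standardized (mean 0, SD 1); the penalty grid runs
#' log-spaced over four decades down from the smallest lambda that zeroes
#' every coefficient, 100 points. lambda* minimizes the mean cross-
#' validated binomial deviance over seeded stratified folds (five by
#' default); the one-standard-error rule is available via `rule = "1se"`.
#' Coefficients are reported on the standardized scale and exponentiated;
#' zero coefficients are reported as OR = 1 with no interval. 95% intervals
#' are percentile bootstrap (500 resamples by default) of the exponentiated
#' coefficient refitted at fixed lambda* — the interval construction is
#' labelled as such in the output, as no standard closed form exists for
#' penalized estimates. The intercept is not penalized (glmnet convention).
#'
#' @inheritParams fit_logistic
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for fold assignment and the bootstrap.
#' @param rule `"1se"` (default) or `"min"` for the penalty choice.
#' @param n_boot_ci bootstrap resamples for the intervals; 0 skips them.
#' @param force_lambda optional fixed penalty; skips cross-validation
#'   (use 0 for the unpenalized limit, `Inf` for full shrinkage).
#' @return object of class `lasso_fit`: `lambda_grid`, `cv_deviance`,
#'   `lambda_star`, `table` (term, estimate, or, ci_low, ci_high),
#'   `ci_method`, `rule`, `n`.
#' @export
fit_lasso_logistic <- function(design, terms = colnames(design$matrix),
                               folds = 5, seed = 1,
                               rule = c("1se", "min"),
                               n_boot_ci = 500,
                               force_lambda = NULL) {
  rule <- match.arg(rule)
  stopifnot(folds >= 2)
  X <- design$matrix[, terms, drop = FALSE]
  y <- design$outcome
  if (length(unique(y)) < 2) stop("outcome has a single class")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant design column(s): ",
         paste(terms[sds == 0], collapse = ", "))
  Xs <- scale(X)
  n <- nrow(Xs)
  # glmnet requires >= 2 columns; a zero pad column never enters the model
  pad <- function(x) if (ncol(x) == 1) cbind(x, `.pad__` = 0) else x

  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100))

  cv_dev <- NULL
  if (is.null(force_lambda)) {
    foldid <- .stratified_folds(y, folds, derive_seed(seed, "lasso:folds"))
    cv <- glmnet::cv.glmnet(pad(Xs), y, family = "binomial", lambda = grid,
                            foldid = foldid, standardize = FALSE,
                            type.measure = "deviance")
    lambda_star <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    cv_dev <- stats::setNames(cv$cvm, signif(cv$lambda, 6))
  } else {
    lambda_star <- force_lambda
  }

  coef_at <- function(x, yy, lam) {
    if (is.infinite(lam))
      return(c(stats::qlogis(mean(yy)), numeric(ncol(x))))
    # descend a short path to the target penalty for solver stability
    path <- unique(c(grid[grid > lam], lam))
    f <- glmnet::glmnet(pad(x), yy, family = "binomial", lambda = path,
                        standardize = FALSE, thresh = 1e-12)
    b <- as.numeric(glmnet::coef.glmnet(f, s = lam, exact = FALSE))
    b[seq_len(ncol(x) + 1)]
  }

  beta <- coef_at(Xs, y, lambda_star)
  names(beta) <- c("(Intercept)", colnames(Xs))

  ci_low <- ci_high <- rep(NA_real_, length(beta))
  if (n_boot_ci > 0) {
    boots <- matrix(NA_real_, n_boot_ci, length(beta))
    for (b in seq_len(n_boot_ci)) {
      set.seed(derive_seed(seed, paste0("lasso:ci:", b)))
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2) next
      xb <- X[idx, , drop = FALSE]
      sb <- apply(xb, 2, stats::sd)
      if (any(sb == 0)) next
      boots[b, ] <- tryCatch(coef_at(scale(xb), y[idx], lambda_star),
                             error = function(e) rep(NA_real_, length(beta)))
    }
    qs <- apply(exp(boots), 2, stats::quantile,
                probs = c(.025, .975), na.rm = TRUE)
    ci_low <- qs[1, ]
    ci_high <- qs[2, ]
  }

  tab <- data.frame(term = names(beta), estimate = unname(beta),
                    or = exp(unname(beta)),
                    ci_low = unname(ci_low), ci_high = unname(ci_high),
                    stringsAsFactors = FALSE)
  zero <- tab$estimate == 0 & tab$term != "(Intercept)"
  tab$or[zero] <- 1
  tab$ci_low[zero] <- NA_real_
  tab$ci_high[zero] <- NA_real_

  structure(list(lambda_grid = grid, cv_deviance = cv_dev,
                 lambda_star = lambda_star, table = tab,
                 ci_method = "percentile bootstrap at fixed lambda*",
                 rule = rule, seed = seed, n = n),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> L1 logistic regression, n = ", x$n,
      ", lambda* = ", signif(x$lambda_star, 4),
      " (", x$rule, " rule)\n", sep = "")
  print(format(x$table, digits = 3), row.names = FALSE)
  cat("CI method:", x$ci_method, "\n")
  invisible(x)
}

#' Forest-plot table of odds ratios
#'
#' One row per model term (intercept excluded): OR, 95% interval bounds and
#' p-value where available, in the order of the selection list. Zeroed
#' LASSO terms appear with OR 1.00 and no interval.
#'
#' @param fit a `model_fit` or `lasso_fit`.
#' @return data frame with columns `term`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
forest_table <- function(fit) {
  stopifnot(inherits(fit, c("model_fit", "lasso_fit")))
  tab <- fit$table
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(term = character(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p = numeric(0)))
  if (is.null(tab$p)) tab$p <- NA_real_
  rownames(tab) <- NULL
  tab[, c("term", "or", "ci_low", "ci_high", "p")]
}

#' Write a forest table as CSV or JSON
#' @param fit a fitted model.
#' @param path output path; `.json` extension selects JSON.
#' @export
write_forest <- function(fit, path) {
  tab <- forest_table(fit)
  if (grepl("\\.json$", path))
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
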