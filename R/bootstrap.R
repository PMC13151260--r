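#' Configuration of the bootstrap graph-stabilization procedure
#'
#' Defaults follow the study design: 1,000 bootstrap iterations, per-
#' iteration retention of effects with absolute value strictly above 0.05,
#' and a sign-stability reporting floor of 0.20.
#'
#' @param n_boot number of bootstrap iterations (>= 1).
#' @param edge_threshold per-iteration and final-graph absolute-effect
#'   retention threshold (strict `>`).
#' @param stability_min minimum sign-stability for the reporting table.
#' @param seed integer root seed; iteration b draws from a child seed
#'   derived from `(seed, b)`, so runs are reproducible and iterations
#'   independent.
#' @param average `"all"` (default) averages effects over all iterations,
#'   zeros included; `"retained"` averages only over iterations where the
#'   edge survived thresholding.
#' @export
ensemble_config <- function(n_boot = 1000, edge_threshold = 0.05,
                            stability_min = 0.20, seed = 1,
                            average = c("all", "retained")) {
  average <- match.arg(average)
  stopifnot(n_boot >= 1, edge_threshold >= 0,
            stability_min >= 0, stability_min <= 1)
  structure(list(n_boot = as.integer(n_boot), edge_threshold = edge_threshold,
                 stability_min = stability_min, seed = as.integer(seed),
                 average = average),
            class = "ensemble_config")
}

#' Learn adjacency matrices on bootstrap resamples
#'
#' Each iteration resamples the rows of `X` with replacement (same n),
#' applies the structure learner, and zeroes entries with absolute effect
#' at or below `edge_threshold`. Learner failures on a resample are
#' recorded and skipped.
#'
#' @param X numeric matrix (patients x variables).
#' @param learner function mapping a data matrix to a square adjacency
#'   matrix; defaults to [direct_lingam()].
#' @param config an [ensemble_config()].
#' @return list of thresholded adjacency matrices, with attributes
#'   `n_failed` and `failures` (messages).
#' @export
bootstrap_adjacencies <- function(X, learner = direct_lingam,
                                  config = ensemble_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- vector("list", config$n_boot)
  failures <- character(0)
  for (b in seq_len(config$n_boot)) {
    set.seed(derive_seed(config$seed, paste0("bootstrap:", b)))
    idx <- sample.int(n, n, replace = TRUE)
    W <- tryCatch(learner(X[idx, , drop = FALSE]), error = function(e) e)
    if (inherits(W, "error")) {
      failures <- c(failures, conditionMessage(W))
      next
    }
    W[abs(W) <= config$edge_threshold] <- 0
    out[[b]] <- W
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("learner failed on every bootstrap resample")
  attr(out, "n_failed") <- length(failures)
  attr(out, "failures") <- failures
  out
}

#' Aggregate bootstrap adjacency matrices into an ensemble graph
#'
#' Per edge: `mean_weight` averages the (thresholded) effects over all
#' iterations, zeros included (set `average = "retained"` in the config to
#' divide by retaining iterations only); `retention_freq` is the fraction
#' of iterations in which the edge survived thresholding; `sign_stability`
#' is the fraction in which it survived *with the sign of its ensemble
#' mean*. Edges of the final DAG are those with `|mean_weight|` strictly
#' above the threshold, passed through bidirectional resolution and cycle
#' repair.
#'
#' @param matrices list of square matrices of equal dimension.
#' @param config an [ensemble_config()].
#' @return object of class `ensemble_graph` with elements `mean_weight`,
#'   `retention_freq`, `sign_stability`, `final_dag`, `n_boot`.
#' @export
aggregate_bootstrap <- function(matrices, config = ensemble_config()) {
  stopifnot(length(matrices) >= 1)
  dims <- vapply(matrices, function(m) dim(m), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("matrices differ in dimension")
  thr <- config$edge_threshold
  n_it <- length(matrices)

  total <- Reduce(`+`, matrices)
  retained <- Reduce(`+`, lapply(matrices, function(m) (abs(m) > thr) * 1))
  mean_weight <- if (config$average == "all") total / n_it
                 else total / pmax(retained, 1)
  retention_freq <- retained / n_it

  s <- sign(mean_weight)
  same_sign <- Reduce(`+`, lapply(matrices, function(m)
    (abs(m) > thr & sign(m) == s) * 1))
  sign_stability <- same_sign / n_it

  if (is.null(rownames(mean_weight))) {
    nms <- paste0("V", seq_len(nrow(mean_weight)))
    dimnames(mean_weight) <- dimnames(retention_freq) <-
      dimnames(sign_stability) <- list(nms, nms)
  }

  g <- graph_from_matrix(mean_weight, thr)
  g <- resolve_bidirectional(g)
  dag <- make_acyclic(g)

  structure(list(mean_weight = mean_weight,
                 retention_freq = retention_freq,
                 sign_stability = sign_stability,
                 final_dag = dag,
                 n_boot = n_it,
                 config = config),
            class = "ensemble_graph")
}

#' @export
print.ensemble_graph <- function(x, ...) {
  cat("<ensemble_graph> ", x$n_boot, " iterations; final DAG: ",
      nrow(x$final_dag$edges), " edges over ",
      length(x$final_dag$nodes), " nodes\n", sep = "")
  invisible(x)
}

#' Bootstrap-stabilized DirectLiNGAM in one call
#'
#' Resample, learn, threshold, average, resolve bidirectional edges, repair
#' cycles. The returned final DAG is asserted acyclic on every run.
#'
#' @inheritParams bootstrap_adjacencies
#' @return an `ensemble_graph`.
#' @export
bootstrap_lingam <- function(X, learner = direct_lingam,
                             config = ensemble_config()) {
  mats <- bootstrap_adjacencies(X, learner, config)
  eg <- aggregate_bootstrap(mats, config)
  eg$n_failed <- attr(mats, "n_failed")
  eg
}

#' Edge-stability reporting table
#'
#' Rows are the edges satisfying BOTH reporting criteria: absolute mean
#' weight strictly above the edge threshold and sign-stability at or above
#' the stability floor. The style tag marks edges with absolute mean
#' weight above 0.20 as `"solid"`, others `"dashed"`.
#'
#' @param eg an `ensemble_graph`.
#' @param config an [ensemble_config()]; defaults to the one stored in `eg`.
#' @return data frame with columns `from`, `to`, `mean_weight`,
#'   `retention_freq`, `sign_stability`, `style`, ordered by decreasing
#'   absolute mean weight.
#' @export
stability_report <- function(eg, config = NULL) {
  stopifnot(inherits(eg, "ensemble_graph"))
  config <- config %||% eg$config
  W <- eg$mean_weight
  keep <- abs(W) > config$edge_threshold &
    eg$sign_stability >= config$stability_min &
    row(W) != col(W)
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(
    from = colnames(W)[idx[, "col"]],
    to = rownames(W)[idx[, "row"]],
    mean_weight = W[idx],
    retention_freq = eg$retention_freq[idx],
    sign_stability = eg$sign_stability[idx],
    stringsAsFactors = FALSE)
  out$style <- ifelse(abs(out$mean_weight) > 0.20, "solid", "dashed")
  out <- out[order(-abs(out$mean_weight), out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}
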