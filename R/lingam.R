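#' Pairwise causal direction measure
#'
#' For a variable pair (x, y), compares the two candidate regressions via
#' the log-likelihood-ratio statistic
#' `M(x -> y) = H(y) + H(r_x|y) - H(x) - H(r_y|x)`,
#' where `r_a|b` is the standardized least-squares residual of `a` on `b`
#' and `H` is the maximum-entropy approximation of differential entropy
#' (`H(u) = H(nu) - 79.047 [E log cosh u - 0.37457]^2 -
#' 7.4129 [E u exp(-u^2/2)]^2`, with `H(nu) = (1 + log 2 pi)/2`). Both
#' inputs are standardized internally. A positive value favors the
#' direction x causes y; the measure is antisymmetric by construction,
#' `M(x -> y) = -M(y -> x)`.
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return a single number.
#' @export
pairwise_direction_measure <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  cpp_pairwise_measure(x, y)
}

#' Estimate a causal ordering by iterative exogenous-variable search
#'
#' DirectLiNGAM ordering: at each step, the candidate whose external
#' influence is most plausibly independent of every other variable's
#' residual is declared most exogenous. Concretely, for each remaining
#' variable i the exogeneity score `T(i) = sum_j min(0, M(i -> j))^2`
#' accumulates only the evidence *against* i being a cause; the variable
#' with the smallest score is appended to the order (ties broken by lowest
#' column index), its linear effect is regressed out of the remaining
#' variables, and the step repeats. Columns are standardized internally,
#' so the order is invariant to positive rescaling of any column.
#'
#' On Gaussian data the direction measure is uninformative and the returned
#' permutation is arbitrary but valid.
#'
#' @param X numeric matrix, rows = observations (must exceed the number of
#'   columns).
#' @return integer permutation of column indices, most exogenous first,
#'   with the column names (if any) as a `names` attribute.
#' @export
estimate_causal_order <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) <= ncol(X)) stop("need more observations than variables")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(X)[sds == 0] %||% which(sds == 0), collapse = ", "))
  ord <- cpp_causal_order(X)
  if (!is.null(colnames(X))) names(ord) <- colnames(X)[ord]
  ord
}

#' Estimate direct effects along a causal ordering
#'
#' Each variable is regressed by ordinary least squares on all of its
#' predecessors in the order; the fitted coefficients populate the
#' adjacency matrix `W`, with `W[i, j]` the direct effect of variable j on
#' variable i and exact zeros for non-predecessors. The first variable in
#' the order has no predecessors and an all-zero row. No pruning is applied
#' here; weak-edge suppression is the job of the bootstrap ensemble
#' threshold downstream.
#'
#' @param X numeric matrix (same columns the order was estimated on).
#' @param order integer permutation from [estimate_causal_order()].
#' @return square adjacency matrix with the column names of `X`.
#' @export
estimate_adjacency <- function(X, order) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (!identical(sort(as.integer(order)), seq_len(p)))
    stop("order is not a permutation of the column indices")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  W <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (t in seq_along(order)[-1]) {
    target <- order[t]
    preds <- order[seq_len(t - 1)]
    A <- Xc[, preds, drop = FALSE]
    G <- crossprod(A)
    if (rcond(G) < 1e-12)
      stop("collinear predecessors when regressing variable ",
           colnames(X)[target] %||% target)
    W[target, preds] <- solve(G, crossprod(A, Xc[, target]))
  }
  W
}

#' Default structure learner: ordering followed by adjacency estimation
#'
#' Convenience composition used as the bootstrap learner.
#'
#' @param X numeric matrix.
#' @return adjacency matrix.
#' @export
direct_lingam <- function(X) {
  estimate_adjacency(X, estimate_causal_order(X))
}

#' Write an adjacency matrix as CSV (rows = effect target)
#' @param W adjacency matrix.
#' @param path output path.
#' @export
write_adjacency_csv <- function(W, path) {
  utils::write.csv(as.data.frame(W), path, row.names = TRUE)
  invisible(path)
}
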