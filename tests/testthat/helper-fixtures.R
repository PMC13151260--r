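# Shared fixture builders. All randomness is seeded by the caller.

# dense lower-triangular SEM: every pair connected, so the causal order is
# fully identifiable
dense_sem <- function(p = 5, seed = 1, lo = 0.3, hi = 0.9) {
  set.seed(seed)
  B <- matrix(0, p, p)
  k <- p * (p - 1) / 2
  B[lower.tri(B)] <- runif(k, lo, hi) * sample(c(-1, 1), k, replace = TRUE)
  sem_spec(paste0("v", seq_len(p)), B)
}

# minimal binary design for the model fits
toy_design <- function(n = 400, seed = 1, p_noise = 0) {
  set.seed(seed)
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.4))
  if (p_noise > 0) {
    Z <- matrix(rbinom(n * p_noise, 1, 0.5), n, p_noise,
                dimnames = list(NULL, paste0("z", seq_len(p_noise))))
    X <- cbind(X, Z)
  }
  y <- rbinom(n, 1, plogis(-0.3 + 1.1 * X[, "a"] - 0.9 * X[, "b"]))
  list(matrix = X, outcome = y)
}

# pure-R reference of the causal-ordering loop, built only on the exported
# pairwise measure; used as an independent oracle for the compiled path
r_reference_order <- function(X) {
  X <- scale(as.matrix(X))
  remaining <- seq_len(ncol(X))
  ord <- integer(0)
  while (length(remaining) > 1) {
    scores <- vapply(remaining, function(i) {
      sum(vapply(setdiff(remaining, i), function(j)
        min(0, pairwise_direction_measure(X[, i], X[, j]))^2, numeric(1)))
    }, numeric(1))
    k <- remaining[order(scores, remaining)[1]]
    ord <- c(ord, k)
    for (j in setdiff(remaining, k)) {
      rho <- stats::cov(X[, j], X[, k]) / stats::var(X[, k])
      X[, j] <- as.numeric(scale(X[, j] - rho * X[, k]))
    }
    remaining <- setdiff(remaining, k)
  }
  c(ord, remaining)
}

# exclusion tallies of the screening flow
flow_counts <- c(11, 15, 59, 5, 7, 10, 4, 4, 9)

fixture_path <- function(file) {
  system.file("extdata", file, package = "ragtcausal", mustWork = TRUE)
}
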