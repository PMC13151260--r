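#' Specify a linear non-Gaussian structural equation model
#'
#' The model is `x = B x + e` with `B[i, j]` the direct effect of variable
#' `j` on variable `i`. `B` must be permutable to strict lower-triangular
#' form (acyclic); the permutation (causal order) is derived here and stored.
#' Noise terms are independent with unit-free scale `s` (the standard
#' deviation): `uniform` on `[-sqrt(3) s, sqrt(3) s]`, `laplace`,
#' `exponential` (centered), or `gaussian`. Uniform is the default: it is
#' bounded, strongly sub-Gaussian, and the customary test noise for LiNGAM
#' identifiability.
#'
#' @param names variable names.
#' @param B square weight matrix, `B[i, j]` = effect of j on i.
#' @param noise single tag or per-variable character vector.
#' @param scales single value or per-variable noise scales (> 0).
#' @return object of class `sem_spec`.
#' @export
sem_spec <- function(names, B,
                     noise = "uniform",
                     scales = 1) {
  p <- length(names)
  stopifnot(is.matrix(B), nrow(B) == p, ncol(B) == p, all(is.finite(B)))
  noise <- rep_len(noise, p)
  scales <- rep_len(scales, p)
  stopifnot(all(noise %in% c("uniform", "laplace", "exponential", "gaussian")),
            all(scales > 0))
  order <- .topological_order(B)
  if (is.null(order))
    stop("B is cyclic: no permutation makes it strictly lower-triangular")
  structure(list(names = names, B = B, noise = noise, scales = scales,
                 order = order),
            class = "sem_spec")
}

# Causal order of B (roots first), or NULL when cyclic.
.topological_order <- function(B) {
  p <- nrow(B)
  remaining <- seq_len(p)
  order <- integer(0)
  while (length(remaining)) {
    # a variable with no remaining parents is next
    roots <- remaining[vapply(remaining, function(i)
      all(B[i, remaining] == 0 | remaining == i), logical(1))]
    if (!length(roots)) return(NULL)
    k <- roots[1L]
    order <- c(order, k)
    remaining <- setdiff(remaining, k)
  }
  order
}

.draw_noise <- function(n, tag, s) {
  switch(tag,
    uniform     = stats::runif(n, -sqrt(3) * s, sqrt(3) * s),
    laplace     = (stats::rexp(n) - stats::rexp(n)) * s / sqrt(2),
    exponential = (stats::rexp(n) - 1) * s,
    gaussian    = stats::rnorm(n, 0, s))
}

#' Simulate data from a linear non-Gaussian SEM
#'
#' Noise is drawn per variable (in variable-index order, so the draws for
#' one variable never depend on how many others exist), then the system
#' `x = B x + e` is solved along the causal order. Deterministic given
#' `(spec, n, seed)`.
#'
#' @param spec a [sem_spec()].
#' @param n number of observations.
#' @param seed integer seed.
#' @return numeric matrix `n x p` with the spec's variable names.
#' @export
simulate_sem <- function(spec, n, seed) {
  stopifnot(inherits(spec, "sem_spec"), n >= 1)
  p <- length(spec$names)
  set.seed(seed)
  E <- matrix(0, n, p)
  for (i in seq_len(p)) E[, i] <- .draw_noise(n, spec$noise[i], spec$scales[i])
  X <- matrix(0, n, p, dimnames = list(NULL, spec$names))
  for (i in spec$order) {
    X[, i] <- E[, i] + X %*% spec$B[i, ]
  }
  X
}

#' Default simulator marginals for the synthetic cohort
#'
#' Level probabilities (ordinals) and quantile anchors (continuous) chosen
#' once to reproduce the published overall baseline summaries of the study
#' population: e.g. age mean 61.2 (SD 11.8), days to robot-training
#' initiation median 42.5 \[34.0, 54.8\], trunk verticality median 3
#' \[2, 3\], ankle dorsiflexion pinned to the scale floor. Nominal
#' variables use exact stratified counts (female 37/126, infarction 47/126,
#' left side 54/126 at n = 126).
#' @keywords internal
.default_marginals <- function() {
  list(
    age = list(kind = "continuous", qfun = function(u) stats::qnorm(u, 61.2, 11.8)),
    days_to_ragt = list(kind = "continuous", qfun = function(u)
      stats::approx(c(0, .25, .5, .75, 1), c(15, 34, 42.5, 54.8, 90),
                    xout = u, rule = 2)$y),
    gaa_baseline = list(kind = "ordinal", values = 1:4,
                        probs = c(.15, .30, .40, .15)),
    sias_hip_flexion = list(kind = "ordinal", values = 0:5,
                            probs = c(.50, .25, .13, .07, .03, .02)),
    sias_knee_extension = list(kind = "ordinal", values = 0:5,
                               probs = c(.55, .25, .10, .05, .03, .02)),
    sias_ankle_dorsiflexion = list(kind = "ordinal", values = 0:5,
                                   probs = c(.80, .10, .05, .03, .01, .01)),
    sias_touch = list(kind = "ordinal", values = 0:3,
                      probs = c(.30, .25, .30, .15)),
    sias_position_sense = list(kind = "ordinal", values = 0:3,
                               probs = c(.35, .25, .25, .15)),
    sias_trunk_verticality = list(kind = "ordinal", values = 0:3,
                                  probs = c(.08, .12, .28, .52)),
    sias_abdominal = list(kind = "ordinal", values = 0:3,
                          probs = c(.30, .28, .27, .15)),
    fim_comprehension = list(kind = "ordinal", values = 1:7,
                             probs = c(.06, .10, .18, .26, .20, .12, .08)),
    fim_expression = list(kind = "ordinal", values = 1:7,
                          probs = c(.08, .18, .14, .22, .20, .10, .08)),
    fim_social_interaction = list(kind = "ordinal", values = 1:7,
                                  probs = c(.05, .09, .16, .20, .25, .15, .10)),
    fim_problem_solving = list(kind = "ordinal", values = 1:7,
                               probs = c(.10, .20, .25, .20, .13, .07, .05)),
    fim_memory = list(kind = "ordinal", values = 1:7,
                      probs = c(.10, .18, .27, .15, .16, .08, .06))
  )
}

#' Default planted causal graph over the baseline variables
#'
#' A sparse DAG over the 15 continuous/ordinal baseline latents shaped like
#' the study's recovered structure: sensory tactile input feeding joint
#' position sense, a proximal-to-distal chain in lower-limb motor items,
#' comprehension driving the other cognitive items, and trunk function
#' driving abdominal strength and baseline walking score. Edge weights are
#' free parameters of the simulator (the study reports its recovered graph
#' without numeric edge weights) and are fixed here once at moderate strength.
#' @keywords internal
.default_planted_graph <- function() {
  nms <- names(.default_marginals())
  p <- length(nms)
  B <- matrix(0, p, p, dimnames = list(nms, nms))
  edge <- function(to, from, w) B[to, from] <<- w
  edge("sias_knee_extension", "sias_hip_flexion", 0.50)
  edge("sias_ankle_dorsiflexion", "sias_knee_extension", 0.45)
  edge("sias_position_sense", "sias_touch", 0.50)
  edge("sias_abdominal", "sias_trunk_verticality", 0.45)
  edge("gaa_baseline", "sias_trunk_verticality", 0.40)
  edge("gaa_baseline", "sias_hip_flexion", 0.30)
  edge("fim_expression", "fim_comprehension", 0.50)
  edge("fim_problem_solving", "fim_comprehension", 0.45)
  edge("fim_memory", "fim_problem_solving", 0.40)
  sem_spec(nms, B)
}

#' Specify a synthetic clinical cohort
#'
#' The simulator draws baseline latents from a planted linear non-Gaussian
#' SEM, maps each latent monotonically onto its instrument scale (rank-based
#' quantile binning, which preserves the dependence structure while matching
#' the target marginals), assigns nominal variables by exact stratified
#' counts, and finally draws the binary outcome from a logistic structural
#' equation over the *median-dichotomized* parents.
#'
#' Default outcome log-odds place the study's three headline effects on
#' their reported scale — trunk verticality `log(7.79)`, joint position
#' sense `log(3.37)`, late training start `log(0.19)` — plus six weaker
#' parent effects, for nine outcome parents in total.
#'
#' @param n_patients cohort size (default 126, the analyzed sample).
#' @param seed integer root seed.
#' @param planted_graph a [sem_spec()] over the baseline latents.
#' @param outcome_coefs named log-odds vector; names must be baseline
#'   variables.
#' @param intercept log-odds intercept, or `NULL` to calibrate it so the
#'   expected outcome prevalence equals `target_prevalence`.
#' @param target_prevalence used only when `intercept` is `NULL`; default
#'   66/126, the study's responder fraction.
#' @param marginals marginal targets, see `.default_marginals`.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 126, seed = 1,
                            planted_graph = .default_planted_graph(),
                            outcome_coefs = c(
                              sias_trunk_verticality = log(7.79),
                              sias_position_sense = log(3.37),
                              days_to_ragt = log(0.19),
                              sias_knee_extension = log(1.6),
                              sias_ankle_dorsiflexion = log(1.5),
                              sias_abdominal = log(1.6),
                              fim_problem_solving = log(1.5),
                              fim_memory = log(1.5),
                              gaa_baseline = log(1.8)),
                            intercept = NULL,
                            target_prevalence = 66 / 126,
                            marginals = .default_marginals()) {
  stopifnot(n_patients >= 2)
  bad <- setdiff(names(outcome_coefs), planted_graph$names)
  if (length(bad))
    stop("outcome_coefs name unknown variables: ", paste(bad, collapse = ", "))
  structure(list(n_patients = n_patients, seed = seed,
                 planted_graph = planted_graph,
                 outcome_coefs = outcome_coefs, intercept = intercept,
                 target_prevalence = target_prevalence,
                 marginals = marginals),
            class = "cohort_sim_spec")
}

# monotone rank-based map of a latent onto its instrument scale
.map_marginal <- function(latent, marg) {
  n <- length(latent)
  u <- (rank(latent, ties.method = "first") - 0.5) / n
  if (marg$kind == "continuous") {
    marg$qfun(u)
  } else {
    idx <- findInterval(u, cumsum(marg$probs)) + 1L
    marg$values[pmin(idx, length(marg$values))]
  }
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_sim_spec()].
#' @return cohort data frame (one row per patient) with attribute `truth`
#'   holding the planted graph, outcome parents and log-odds used.
#' @seealso [cohort_sim_spec()] for the generative model.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  n <- spec$n_patients
  latents <- simulate_sem(spec$planted_graph, n,
                          derive_seed(spec$seed, "cohort:latents"))

  cohort <- data.frame(row.names = seq_len(n))
  for (nm in names(spec$marginals))
    cohort[[nm]] <- .map_marginal(latents[, nm], spec$marginals[[nm]])

  # nominal variables: exact stratified counts, permuted
  nominal <- list(
    sex = list(levels = c("male", "female"), p = 37 / 126),
    stroke_type = list(levels = c("hemorrhage", "infarction"), p = 47 / 126),
    affected_side = list(levels = c("right", "left"), p = 54 / 126))
  for (nm in names(nominal)) {
    k <- round(nominal[[nm]]$p * n)
    v <- rep(nominal[[nm]]$levels, c(n - k, k))
    set.seed(derive_seed(spec$seed, paste0("cohort:nominal:", nm)))
    cohort[[nm]] <- sample(v)
  }

  # outcome: logistic over median-dichotomized parents
  parents <- names(spec$outcome_coefs)
  codes <- vapply(parents, function(nm)
    .code_with_fallback(as.numeric(cohort[[nm]]))$code, integer(n))
  eta0 <- drop(codes %*% spec$outcome_coefs)
  intercept <- spec$intercept %||%
    (stats::qlogis(spec$target_prevalence) -
       sum(spec$outcome_coefs * colMeans(codes)))
  pr <- stats::plogis(intercept + eta0)
  set.seed(derive_seed(spec$seed, "cohort:outcome"))
  responder <- stats::rbinom(n, 1, pr)

  # 4-week walking score consistent with the binary outcome
  set.seed(derive_seed(spec$seed, "cohort:gaa4wk"))
  gaa_hi <- sample(5:7, n, replace = TRUE, prob = c(.6, .3, .1))
  gaa_lo <- sample(1:4, n, replace = TRUE, prob = c(.15, .35, .35, .15))
  cohort$gaa_4wk <- ifelse(responder == 1, gaa_hi, gaa_lo)

  cohort <- cohort[, c("age", "sex", "stroke_type", "affected_side",
                       setdiff(names(spec$marginals), "age"), "gaa_4wk")]
  attr(cohort, "truth") <- list(parents = parents,
                                coefs = spec$outcome_coefs,
                                intercept = intercept,
                                planted_graph = spec$planted_graph)
  cohort
}

#' Generate the 250-record screening fixture
#'
#' Builds a pre-eligibility roster whose pass through [apply_screening()]
#' reproduces the study's selection flow exactly: 250 screened, exclusions
#' 11 / 15 / 59 / 5 / 7 / 10 / 4 / 4 / 9 in cascade order, 126 included.
#' Records excluded for reason k satisfy every earlier criterion, so
#' first-failure attribution recovers the published tallies. Row order is
#' shuffled by the seed.
#'
#' @param seed integer seed.
#' @return data frame of screening records.
#' @export
generate_screening_fixture <- function(seed = 1) {
  counts <- c(11, 15, 59, 5, 7, 10, 4, 4, 9)
  n_inc <- 126
  n <- n_inc + sum(counts)

  set.seed(derive_seed(seed, "screening:attributes"))
  rec <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    supratentorial = TRUE,
    first_stroke = TRUE,
    sias_lower_limb_motor_total = sample(0:5, n, replace = TRUE),
    baseline_gaa = sample(1:4, n, replace = TRUE, prob = c(.2, .35, .3, .15)),
    subarachnoid = FALSE,
    neuro_comorbidity = FALSE,
    declined = FALSE,
    assessment_incomplete = FALSE,
    sessions_completed = sample(10:28, n, replace = TRUE),
    stringsAsFactors = FALSE)

  i <- n_inc
  take <- function(k) { rows <- i + seq_len(counts[k]); i <<- i + counts[k]; rows }
  rec$supratentorial[take(1)] <- FALSE
  rec$first_stroke[take(2)] <- FALSE
  rec$sias_lower_limb_motor_total[take(3)] <- sample(6:15, counts[3], replace = TRUE)
  rec$baseline_gaa[take(4)] <- sample(5:7, counts[4], replace = TRUE)
  rec$subarachnoid[take(5)] <- TRUE
  rec$neuro_comorbidity[take(6)] <- TRUE
  rec$declined[take(7)] <- TRUE
  rec$assessment_incomplete[take(8)] <- TRUE
  rec$sessions_completed[take(9)] <- sample(0:9, counts[9], replace = TRUE)

  set.seed(derive_seed(seed, "screening:shuffle"))
  rec <- rec[sample.int(n), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write simulator specs as JSON
#' @param spec a `sem_spec` or `cohort_sim_spec`.
#' @param path output path.
#' @export
write_spec_json <- function(spec, path) {
  x <- unclass(spec)
  x$planted_graph <- if (!is.null(x$planted_graph)) unclass(x$planted_graph)
  x <- x[!vapply(x, is.function, logical(1))]
  if (!is.null(x$marginals))
    x$marginals <- lapply(x$marginals, function(m) m[names(m) != "qfun"])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
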