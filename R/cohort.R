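#' Variable roster for the gait-training cohort
#'
#' Returns the default roster of analysis variables: name, measurement kind
#' (`nominal`, `ordinal`, `continuous`), model role (`exposure`, `outcome`,
#' `excluded`) and, for nominal variables, the ordered level labels. Dummy
#' coding and the descriptive table both report the *second* level of a
#' nominal variable (female, infarction, left side).
#'
#' Instrument ranges: SIAS lower-limb motor items are scored 0-5, SIAS
#' sensory and trunk items 0-3, FIM cognitive items 1-7, and the walking
#' independence scale (GAA) 1-7. The binary study outcome is walking with
#' supervision or better, i.e. a 4-week GAA score of at least 5.
#'
#' @return a data frame with columns `name`, `kind`, `role` and a list
#'   column `levels`.
#' @export
default_variable_specs <- function() {
  spec <- function(name, kind, role, levels = NULL, summary = NA) {
    data.frame(name = name, kind = kind, role = role,
               levels = I(list(levels)), summary = summary,
               stringsAsFactors = FALSE)
  }
  rbind(
    spec("age",                  "continuous", "exposure"),
    spec("sex",                  "nominal",    "exposure", c("male", "female")),
    spec("stroke_type",          "nominal",    "exposure", c("hemorrhage", "infarction")),
    spec("affected_side",        "nominal",    "exposure", c("right", "left")),
    spec("days_to_ragt",         "continuous", "exposure", summary = "median_iqr"),
    spec("gaa_baseline",         "ordinal",    "exposure"),
    spec("sias_hip_flexion",     "ordinal",    "exposure"),
    spec("sias_knee_extension",  "ordinal",    "exposure"),
    spec("sias_ankle_dorsiflexion", "ordinal", "exposure"),
    spec("sias_touch",           "ordinal",    "exposure"),
    spec("sias_position_sense",  "ordinal",    "exposure"),
    spec("sias_trunk_verticality", "ordinal",  "exposure"),
    spec("sias_abdominal",       "ordinal",    "exposure"),
    spec("fim_comprehension",    "ordinal",    "exposure"),
    spec("fim_expression",       "ordinal",    "exposure"),
    spec("fim_social_interaction", "ordinal",  "exposure"),
    spec("fim_problem_solving",  "ordinal",    "exposure"),
    spec("fim_memory",           "ordinal",    "exposure"),
    spec("gaa_4wk",              "ordinal",    "outcome")
  )
}

#' Instrument score ranges, used for validation
#' @keywords internal
.score_ranges <- list(
  gaa_baseline = c(1, 7), gaa_4wk = c(1, 7),
  sias_hip_flexion = c(0, 5), sias_knee_extension = c(0, 5),
  sias_ankle_dorsiflexion = c(0, 5),
  sias_touch = c(0, 3), sias_position_sense = c(0, 3),
  sias_trunk_verticality = c(0, 3), sias_abdominal = c(0, 3),
  fim_comprehension = c(1, 7), fim_expression = c(1, 7),
  fim_social_interaction = c(1, 7), fim_problem_solving = c(1, 7),
  fim_memory = c(1, 7)
)

#' Exclusion reasons of the screening cascade, in application order
#' @export
screening_reasons <- function() {
  c("non-supratentorial lesion", "recurrent stroke", "SIAS motor > 5",
    "GAA > 4", "subarachnoid hemorrhage", "neurological comorbidity",
    "declined participation", "assessment incomplete", "<10 sessions")
}

#' Apply the eligibility screening cascade
#'
#' Filters pre-eligibility records through the study's exclusion criteria in
#' their stated order: non-supratentorial lesion, recurrent stroke, SIAS
#' lower-limb motor total above 5, baseline walking score above 4 (already
#' walking with supervision), subarachnoid hemorrhage, neurological
#' comorbidity, declined participation, incomplete post-intervention
#' assessment, fewer than 10 robot sessions. Each record is tallied under
#' the *first* criterion it fails, so counts are order-dependent and
#' `nrow(included) + sum(tally) == nrow(records)` always holds.
#'
#' @param records data frame of screening records with columns `patient_id`,
#'   `supratentorial`, `first_stroke`, `sias_lower_limb_motor_total`,
#'   `baseline_gaa`, `subarachnoid`, `neuro_comorbidity`, `declined`,
#'   `assessment_incomplete`, `sessions_completed`.
#' @return list with `included` (data frame of surviving records), `tally`
#'   (named integer vector over [screening_reasons()]) and `n_screened`.
#' @export
apply_screening <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  needed <- c("patient_id", "supratentorial", "first_stroke",
              "sias_lower_limb_motor_total", "baseline_gaa", "subarachnoid",
              "neuro_comorbidity", "declined", "assessment_incomplete",
              "sessions_completed")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("screening records lack columns: ", paste(missing_cols, collapse = ", "))

  bad <- !is.finite(records$sias_lower_limb_motor_total) |
    records$sias_lower_limb_motor_total < 0 |
    records$sias_lower_limb_motor_total > 15 |
    !is.finite(records$baseline_gaa) |
    records$baseline_gaa < 1 | records$baseline_gaa > 7 |
    !is.finite(records$sessions_completed) | records$sessions_completed < 0
  for (fl in c("supratentorial", "first_stroke", "subarachnoid",
               "neuro_comorbidity", "declined", "assessment_incomplete")) {
    bad <- bad | is.na(records[[fl]]) | !is.logical(records[[fl]])
  }
  if (any(bad))
    stop("malformed screening record(s): ",
         paste(records$patient_id[bad], collapse = ", "))

  fails <- cbind(
    !records$supratentorial,
    !records$first_stroke,
    records$sias_lower_limb_motor_total > 5,
    records$baseline_gaa > 4,
    records$subarachnoid,
    records$neuro_comorbidity,
    records$declined,
    records$assessment_incomplete,
    records$sessions_completed < 10
  )
  # first failing criterion, 0 if none
  first_fail <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w)) w[1L] else 0L
  })
  reasons <- screening_reasons()
  tally <- stats::setNames(
    vapply(seq_along(reasons), function(k) sum(first_fail == k), integer(1)),
    reasons)
  list(included = records[first_fail == 0L, , drop = FALSE],
       tally = tally,
       n_screened = nrow(records))
}

#' Define the binary walking outcome
#'
#' The responder outcome is walking with supervision or better at the end of
#' the 4-week training period, i.e. a 4-week GAA score >= 5.
#'
#' @param cohort cohort data frame containing `gaa_4wk` (integer 1-7).
#' @return integer 0/1 vector.
#' @export
define_outcome <- function(cohort) {
  g <- cohort$gaa_4wk
  if (is.null(g)) stop("cohort has no 'gaa_4wk' column")
  if (any(!is.finite(g) | g < 1 | g > 7))
    stop("gaa_4wk outside the 1-7 scale")
  as.integer(g >= 5)
}

#' Dichotomize a variable at its sample median
#'
#' Splits a continuous or ordinal variable at its sample median (quartile
#' type 7, i.e. linear interpolation). By default the high group is strictly
#' above the median (`direction = "greater"`): several SIAS items have their
#' median at the scale floor, where a `>=` split would produce a degenerate
#' all-one column. The `"geq"` direction is available for variables where
#' the opposite convention is wanted.
#'
#' @param values numeric vector, length >= 2.
#' @param direction `"greater"` codes 1 iff value > median; `"geq"` codes 1
#'   iff value >= median.
#' @return list with `code` (integer 0/1), `split` (the median),
#'   `direction`, and `degenerate` (TRUE when the coded column is constant,
#'   in which case a warning is emitted).
#' @export
dichotomize_at_median <- function(values, direction = c("greater", "geq")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values), length(values) >= 2)
  if (any(!is.finite(values))) stop("non-finite values in input")
  m <- stats::median(values)
  code <- if (direction == "greater") as.integer(values > m)
          else as.integer(values >= m)
  degenerate <- length(unique(code)) < 2L
  if (degenerate)
    warning("dichotomized column is constant (split at ", m, ")")
  list(code = code, split = m, direction = direction, degenerate = degenerate)
}

# Median split with automatic direction fallback at scale boundaries:
# the preferred direction is tried first; if its coded column is constant
# the opposite direction is used. Returns the dichotomize_at_median()
# result with the direction actually applied.
.code_with_fallback <- function(values, direction = "greater") {
  quiet <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  d <- quiet(dichotomize_at_median(values, direction))
  if (d$degenerate) {
    other <- if (direction == "greater") "geq" else "greater"
    d2 <- quiet(dichotomize_at_median(values, other))
    if (!d2$degenerate) return(d2)
  }
  d
}

#' Build the binary analysis design from a cohort table
#'
#' Nominal variables are dummy-coded 0/1 against their second level; ordinal
#' and continuous variables are dichotomized at the sample median via
#' [dichotomize_at_median()]. When the preferred split direction is
#' degenerate because the median sits at a scale boundary — strict `>` is
#' degenerate at the ceiling (e.g. trunk verticality, median 3 on a 0-3
#' scale), `>=` at the floor (e.g. ankle dorsiflexion, median 0) — the
#' opposite direction is used for that column; the direction actually
#' applied is recorded per column in the coding log. Columns degenerate in
#' both directions (constant variables) are dropped with a warning. The
#' outcome column is walking-with-supervision per [define_outcome()].
#'
#' @param cohort cohort data frame.
#' @param specs variable roster, defaults to [default_variable_specs()].
#' @param direction median-split direction, see [dichotomize_at_median()].
#' @return an object of class `binary_design`: list with `matrix` (patients
#'   x coded variables, 0/1), `outcome` (0/1 vector) and `coding_log` (one
#'   row per variable: kind, split point, direction, degenerate flag).
#' @export
code_design <- function(cohort, specs = default_variable_specs(),
                        direction = c("greater", "geq")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(cohort))
  if (anyNA(cohort)) stop("cohort contains missing values")
  expo <- specs[specs$role == "exposure", , drop = FALSE]
  absent <- setdiff(expo$name, names(cohort))
  if (length(absent))
    stop("cohort lacks variables: ", paste(absent, collapse = ", "))

  cols <- list()
  log_rows <- list()
  for (i in seq_len(nrow(expo))) {
    nm <- expo$name[i]; kind <- expo$kind[i]
    v <- cohort[[nm]]
    if (kind == "nominal") {
      lev <- expo$levels[[i]]
      if (length(lev) < 2) stop("nominal variable ", nm, " needs >= 2 levels")
      code <- as.integer(as.character(v) == lev[2L])
      degenerate <- length(unique(code)) < 2L
      log_rows[[nm]] <- data.frame(
        variable = nm, kind = kind, split = NA_real_,
        direction = paste0("== ", lev[2L]), degenerate = degenerate)
    } else {
      d <- .code_with_fallback(as.numeric(v), direction)
      code <- d$code
      degenerate <- d$degenerate
      log_rows[[nm]] <- data.frame(
        variable = nm, kind = kind, split = d$split,
        direction = if (d$direction == "greater") "> median" else ">= median",
        degenerate = degenerate)
    }
    if (degenerate) {
      warning("dropping degenerate coded column: ", nm)
    } else {
      cols[[nm]] <- code
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- NULL
  structure(list(matrix = mat,
                 outcome = define_outcome(cohort),
                 coding_log = do.call(rbind, c(log_rows, make.row.names = FALSE))),
            class = "binary_design")
}

#' @export
print.binary_design <- function(x, ...) {
  cat("<binary_design> ", nrow(x$matrix), " patients x ", ncol(x$matrix),
      " coded variables; outcome prevalence ",
      sprintf("%.3f", mean(x$outcome)), "\n", sep = "")
  dropped <- x$coding_log$variable[x$coding_log$degenerate]
  if (length(dropped))
    cat("dropped degenerate:", paste(dropped, collapse = ", "), "\n")
  invisible(x)
}

.fmt1 <- function(x) sprintf("%.1f", x)

#' Descriptive baseline table, overall and by outcome group
#'
#' Continuous variables are reported as mean (SD), ordinal variables as
#' median \[first quartile, third quartile\] with quartiles by linear
#' interpolation (quantile type 7), and nominal variables as n (%) of the
#' reported level (female, infarction, left side). All display values are
#' rounded to one decimal.
#'
#' @param cohort cohort data frame.
#' @param specs variable roster.
#' @param outcome optional 0/1 vector; defaults to [define_outcome()] on the
#'   cohort. Group 0 is labelled "walking with physical assistance", group 1
#'   "walking with supervision".
#' @return data frame with columns `variable`, `stat`, `overall`,
#'   `assistance`, `supervision` (formatted strings), plus the group sizes
#'   as an attribute `n`.
#' @export
descriptive_table <- function(cohort, specs = default_variable_specs(),
                              outcome = NULL) {
  if (is.null(outcome)) outcome <- define_outcome(cohort)
  stopifnot(length(outcome) == nrow(cohort))
  groups <- list(overall = rep(TRUE, nrow(cohort)),
                 assistance = outcome == 0,
                 supervision = outcome == 1)

  cell <- function(v, kind, lev, idx) {
    v <- v[idx]
    if (length(v) == 0) return("-")
    switch(kind,
      continuous = sprintf("%s (%s)", .fmt1(mean(v)),
                           .fmt1(if (length(v) > 1) stats::sd(v) else 0)),
      ordinal = {
        q <- stats::quantile(as.numeric(v), c(.25, .5, .75), type = 7, names = FALSE)
        sprintf("%s [%s, %s]", .fmt1(q[2]), .fmt1(q[1]), .fmt1(q[3]))
      },
      nominal = {
        n1 <- sum(as.character(v) == lev[2L])
        sprintf("%d (%s)", n1, .fmt1(100 * n1 / length(v)))
      })
  }

  rows <- specs[specs$role != "excluded", , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    nm <- rows$name[i]; kind <- rows$kind[i]; lev <- rows$levels[[i]]
    # per-variable display override (e.g. skewed days-to-training is
    # summarized as median [IQR] although it is continuous)
    if (!is.null(rows$summary) && !is.na(rows$summary[i]) &&
        rows$summary[i] == "median_iqr") kind <- "ordinal"
    stat <- switch(kind, continuous = "mean (SD)",
                   ordinal = "median [IQR]",
                   nominal = paste0("n (%) ", lev[2L]))
    cells <- vapply(groups, function(idx) cell(cohort[[nm]], kind, lev, idx),
                    character(1))
    data.frame(variable = nm, stat = stat,
               overall = cells[["overall"]],
               assistance = cells[["assistance"]],
               supervision = cells[["supervision"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  attr(tab, "n") <- c(overall = nrow(cohort),
                      assistance = sum(outcome == 0),
                      supervision = sum(outcome == 1))
  tab
}

#' Read a cohort table from CSV
#'
#' Header row must carry the variable names; missing values are rejected
#' (the study data were complete) and instrument score ranges are checked.
#'
#' @param path CSV file path.
#' @param specs variable roster used for validation.
#' @export
read_cohort_csv <- function(path, specs = default_variable_specs()) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (anyNA(cohort))
    stop("cohort CSV contains missing values: ", path)
  for (nm in intersect(names(.score_ranges), names(cohort))) {
    rng <- .score_ranges[[nm]]
    v <- cohort[[nm]]
    if (any(v < rng[1] | v > rng[2]))
      stop(nm, " outside its instrument range [", rng[1], ", ", rng[2], "]")
  }
  cohort
}

#' @rdname read_cohort_csv
#' @param cohort cohort data frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a screening tally or coding log as JSON
#' @param x named vector or data frame.
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
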