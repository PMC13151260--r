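nm2 <- c("x", "y")
mat2 <- function(w) matrix(c(0, w, 0, 0), 2, 2, dimnames = list(nm2, nm2))

test_that("a single bootstrap iteration equals the thresholded learner output", {
  sp <- dense_sem(3, seed = 1)
  X <- simulate_sem(sp, 300, seed = 1)
  cfg <- ensemble_config(n_boot = 1, edge_threshold = 0.05, seed = 17)
  mats <- bootstrap_adjacencies(X, direct_lingam, cfg)
  expect_length(mats, 1)
  # reproduce the resample that iteration 1 drew
  set.seed(derive_seed(cfg$seed, "bootstrap:1"))
  idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
  W <- direct_lingam(X[idx, ])
  W[abs(W) <= 0.05] <- 0
  expect_equal(mats[[1]], W)
})

test_that("a degenerate constant learner passes through thresholding unchanged", {
  M <- matrix(c(0, 0.3, 0.02, 0), 2, 2, dimnames = list(nm2, nm2))
  mats <- bootstrap_adjacencies(matrix(rnorm(40), 20, 2), function(X) M,
                                ensemble_config(n_boot = 5, seed = 2))
  Mthr <- M; Mthr[abs(Mthr) <= 0.05] <- 0
  for (m in mats) expect_equal(m, Mthr)
})

test_that("learner failures are recorded and skipped", {
  k <- 0
  flaky <- function(X) {
    k <<- k + 1
    if (k %% 2 == 0) stop("boom")
    mat2(0.3)
  }
  mats <- bootstrap_adjacencies(matrix(rnorm(40), 20, 2), flaky,
                                ensemble_config(n_boot = 6, seed = 3))
  expect_length(mats, 3)
  expect_equal(attr(mats, "n_failed"), 3)
})

test_that("aggregation arithmetic matches hand-computed two-iteration cases", {
  cfg <- ensemble_config(n_boot = 2, seed = 1)
  eg <- aggregate_bootstrap(list(mat2(0.2), mat2(0)), cfg)
  expect_equal(eg$mean_weight["y", "x"], 0.1)
  expect_equal(eg$retention_freq["y", "x"], 0.5)
  expect_equal(eg$sign_stability["y", "x"], 0.5)

  # identical matrices: retention in {0, 1} and sign-stability equals it
  eg2 <- aggregate_bootstrap(list(mat2(0.2), mat2(0.2)), cfg)
  expect_true(all(eg2$retention_freq %in% c(0, 1)))
  expect_equal(eg2$sign_stability, eg2$retention_freq)

  # cancellation: opposite signs average to zero and the edge disappears
  eg3 <- aggregate_bootstrap(list(mat2(0.2), mat2(-0.2)), cfg)
  expect_equal(eg3$mean_weight["y", "x"], 0)
  expect_equal(nrow(eg3$final_dag$edges), 0)

  # retained-only averaging divides by retaining iterations
  cfg_r <- ensemble_config(n_boot = 2, seed = 1, average = "retained")
  eg4 <- aggregate_bootstrap(list(mat2(0.2), mat2(0)), cfg_r)
  expect_equal(eg4$mean_weight["y", "x"], 0.2)
})

test_that("sign stability never exceeds retention and fractions are proper", {
  set.seed(5)
  mats <- replicate(30, {
    m <- matrix(runif(16, -0.3, 0.3), 4, 4); diag(m) <- 0
    m[abs(m) <= 0.05] <- 0
    m
  }, simplify = FALSE)
  eg <- aggregate_bootstrap(mats, ensemble_config(n_boot = 30, seed = 1))
  expect_true(all(eg$sign_stability <= eg$retention_freq + 1e-12))
  expect_true(all(eg$retention_freq >= 0 & eg$retention_freq <= 1))
})

test_that("bidirectional pairs resolve to the stronger direction", {
  g <- weighted_digraph(c("a", "b"),
                        data.frame(from = c("a", "b"), to = c("b", "a"),
                                   weight = c(0.3, 0.2)))
  r <- resolve_bidirectional(g)
  expect_equal(r$edges$from, "a")
  expect_equal(attr(r, "resolved")$from, "b")

  # acyclic graph untouched
  g2 <- weighted_digraph(c("a", "b", "c"),
                         data.frame(from = c("a", "b"), to = c("b", "c"),
                                    weight = c(0.3, 0.2)))
  expect_equal(resolve_bidirectional(g2)$edges, g2$edges)

  # exact tie: lexicographic keep, with a warning
  g3 <- weighted_digraph(c("a", "b"),
                         data.frame(from = c("a", "b"), to = c("b", "a"),
                                    weight = c(0.2, -0.2)))
  expect_warning(r3 <- resolve_bidirectional(g3), "lexicographic")
  expect_equal(r3$edges$from, "a")
})

test_that("cycle repair removes the weakest edge within each cycle", {
  g <- weighted_digraph(c("a", "b", "c"),
                        data.frame(from = c("a", "b", "c"),
                                   to = c("b", "c", "a"),
                                   weight = c(0.3, 0.2, 0.1)))
  d <- make_acyclic(g)
  expect_equal(nrow(d$edges), 2)
  expect_equal(attr(d, "removed")$from, "c")

  # already acyclic: unchanged
  g2 <- weighted_digraph(c("a", "b", "c"),
                         data.frame(from = c("a", "a"), to = c("b", "c"),
                                    weight = c(0.3, 0.2)))
  expect_equal(make_acyclic(g2)$edges, g2$edges)

  # two disjoint 2-cycles: exactly the weaker edge of each goes
  g3 <- weighted_digraph(c("a", "b", "c", "d"),
                         data.frame(from = c("a", "b", "c", "d"),
                                    to   = c("b", "a", "d", "c"),
                                    weight = c(0.4, 0.1, 0.2, 0.5)))
  d3 <- make_acyclic(g3)
  rem <- attr(d3, "removed")
  expect_equal(nrow(rem), 2)
  expect_setequal(paste(rem$from, rem$to), c("b a", "c d"))
})

test_that("outcome parents are returned strongest-first", {
  g <- weighted_digraph(c("p", "q", "out"),
                        data.frame(from = c("p", "q"), to = c("out", "out"),
                                   weight = c(0.1, 0.4)))
  expect_equal(as.character(select_outcome_parents(g, "out")), c("q", "p"))
  g0 <- weighted_digraph(c("p", "out"),
                         data.frame(from = "out", to = "p", weight = 0.2))
  expect_length(select_outcome_parents(g0, "out"), 0)
  expect_error(select_outcome_parents(g0, "nope"), "not in graph")
})

test_that("stability report applies both criteria with strict thresholds", {
  W <- function(w) matrix(c(0, w, 0, 0), 2, 2, dimnames = list(nm2, nm2))
  cfg <- ensemble_config(n_boot = 100, seed = 1)
  # 6 retaining iterations of 0.06/94 zeros -> sign stability 0.06 < 0.20
  mats <- c(replicate(6, W(1), simplify = FALSE),
            replicate(94, W(0), simplify = FALSE))
  eg <- aggregate_bootstrap(mats, cfg)
  expect_equal(eg$mean_weight["y", "x"], 0.06)
  expect_equal(nrow(stability_report(eg)), 0)

  # strong stable edge: included and solid
  mats2 <- c(replicate(90, W(0.28), simplify = FALSE),
             replicate(10, W(0), simplify = FALSE))
  eg2 <- aggregate_bootstrap(mats2, cfg)
  rep2 <- stability_report(eg2)
  expect_equal(nrow(rep2), 1)
  expect_equal(rep2$style, "solid")
  expect_equal(rep2$sign_stability, 0.9)

  # |mean| exactly at the threshold is excluded (strict >)
  mats3 <- replicate(10, W(0.05 + 1e-9), simplify = FALSE)
  eg3 <- aggregate_bootstrap(mats3, cfg)
  eg3$mean_weight["y", "x"] <- 0.05
  expect_equal(nrow(stability_report(eg3)), 0)
})

test_that("the ensemble pipeline recovers a 3-variable SEM", {
  B <- matrix(0, 3, 3); B[2, 1] <- 0.8; B[3, 2] <- 0.7
  X <- simulate_sem(sem_spec(c("a", "b", "c"), B), 500, seed = 7)
  eg <- bootstrap_lingam(X, config = ensemble_config(n_boot = 200, seed = 5))
  expect_gt(eg$retention_freq["b", "a"], 0.9)
  expect_gt(eg$retention_freq["c", "b"], 0.9)
  expect_lt(eg$retention_freq["a", "c"], 0.2)
  # determinism under the same config
  eg2 <- bootstrap_lingam(X, config = ensemble_config(n_boot = 200, seed = 5))
  expect_equal(eg$mean_weight, eg2$mean_weight)
})

test_that("graph exports are readable text", {
  g <- weighted_digraph(c("a", "b"),
                        data.frame(from = "a", to = "b", weight = 0.42))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_edges_csv(g, tmp)
  expect_equal(read.csv(tmp)$weight, 0.42)
  tmpd <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, tmpd)
  expect_match(paste(readLines(tmpd), collapse = "\n"), "\"a\" -> \"b\"")
  tmpj <- withr::local_tempfile(fileext = ".json")
  write_edges_json(g, tmpj)
  expect_equal(jsonlite::read_json(tmpj)$edges[[1]]$weight, 0.42)
})
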