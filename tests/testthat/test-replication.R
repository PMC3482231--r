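# Cheap structural checks of the replication harnesses; the full
# reduced-scale studies live in test-acceptance.R.

tiny_cfg <- function(seed) {
  fit_config(n_individual_samples = 60, n_group_samples = 200, burn_in = 80,
             seed = seed)
}

test_that("the cluster-recovery harness aggregates per group size", {
  out <- run_simulation1(group_sizes = 2, runs_per_size = 1, n_infants = 6,
                         config = tiny_cfg(41))
  expect_equal(nrow(out$summary), 1)
  expect_equal(out$summary$n_groups, 2)
  expect_true(out$runs$misclassification >= 0 &&
                out$runs$misclassification <= 1)
  # vacuous sweep
  empty <- run_simulation1(group_sizes = 1:2, runs_per_size = 0,
                           config = tiny_cfg(1))
  expect_equal(nrow(empty$summary), 0)
})

test_that("the factorial harness reports per-factor regressions", {
  cells <- data.frame(object = c(0, 1), cue = c(0, 1), assoc = c(0, 0.5))
  out <- run_simulation2(cells, n_infants = 4, config = tiny_cfg(42))
  expect_equal(nrow(out$recovery), 2)
  expect_setequal(out$stats$factor, c("object", "cue", "assoc"))
  expect_true(all(is.finite(out$stats$slope)))
})

test_that("the learning-function harness scores both polynomial terms", {
  out <- run_simulation3(kinds = "u_down", runs_per_kind = 1, n_infants = 4,
                         config = tiny_cfg(43))
  expect_equal(out$summary$kind, "u_down")
  expect_true(is.logical(out$runs$a1_nonzero))
  expect_true(out$linear_type2_rate >= 0 && out$linear_type2_rate <= 1)
})

test_that("replication runs are reproducible from their logged seeds", {
  a <- run_simulation1(group_sizes = 1, runs_per_size = 2, n_infants = 5,
                       config = tiny_cfg(44))
  b <- run_simulation1(group_sizes = 1, runs_per_size = 2, n_infants = 5,
                       config = tiny_cfg(44))
  expect_identical(a, b)
})

test_that("habituation comparison reports verdicts for both families", {
  gen <- generate_sim1_dataset(4, 1, seed = 45)
  out <- run_habituation_comparison(gen$dataset, gen$design, tiny_cfg(46))
  expect_named(out$assoc_nonzero, c("a1", "a2"))
  expect_named(out$habit_nonzero, c("h1", "h2"))
  expect_true(all(out$chain$config$model_spec$include_habituation))
})

test_that("R step functions and the compiled driver see the same posterior", {
  # one infant, strong baseline signal: compare posterior medians from a
  # chain composed of the exported single-step moves against the fitted
  # driver chain
  d <- build_design("square", 2, 4, seed = 47)
  spec <- model_spec()
  p <- cognitive_params(baseline = c(1.5, -1, 0, .5, -1.5),
                        beta_object = 1, max_degree = 2)
  ds <- list(simulate_infant(p, spec, d, seed = 48))
  pre <- lapply(ds, gazelink:::precompute_infant, design = d, spec = spec)
  cfg <- fit_config(proposal_scales = c(baseline = .15, object = .15,
                                        cue = .15, assoc = .08, habit = .08))
  set.seed(49)
  st <- simple_state(1)
  n_iter <- 1200
  keep <- matrix(0, n_iter, 2)
  for (s in seq_len(n_iter)) {
    st <- gibbs_reassign_infant(st, 1, ds, d, spec, precomp = pre)
    for (k in seq_along(st$tables))
      st <- update_table_params(st, k, ds, d, cfg, precomp = pre)
    st <- update_hyperparams(st, spec)
    keep[s, ] <- st$tables[[1]][c("b_TL", "beta_object")]
  }
  r_med <- apply(keep[401:n_iter, ], 2, median)
  ch <- fit_gaze_model(ds, d, fit_config(n_individual_samples = 200,
                                         n_group_samples = 1200,
                                         burn_in = 400, seed = 50))
  cpp_med <- apply(do.call(rbind, lapply(ch$tables, function(m) m[1, ])), 2,
                   median)[c(1, 6)]
  expect_equal(r_med, unname(cpp_med), tolerance = 0.2)
})

test_that("learning is attributed to the correct family", {
  # habituation-only ground truth: the association family must stay pinned
  spec_h <- model_spec(include_association = FALSE, include_habituation = TRUE)
  set.seed(79)
  d <- build_design("square", 4, 6, seed = 79)
  ph <- cognitive_params(baseline = c(runif(4, -1, 1), runif(1, -2, 0)),
                         beta_object = .5, beta_cue = .5,
                         habit_coeffs = c(.4, 0), max_degree = 2)
  ds <- lapply(1:10, function(k)
    simulate_infant(ph, spec_h, d, seed = 790 + k, sprintf("i%d", k)))
  hb <- run_habituation_comparison(ds, d, fit_config(seed = 80))
  expect_false(any(hb$assoc_nonzero))
  expect_true(hb$habit_nonzero[["h1"]])
  expect_equal(unname(hb$habit_median[["h1"]]), 0.4, tolerance = 0.1)
  # association-only ground truth: the habituation family must stay pinned
  spec_a <- model_spec()
  set.seed(81)
  d2 <- build_design("square", 4, 6, seed = 81)
  pa <- cognitive_params(baseline = c(runif(4, -1, 1), runif(1, -2, 0)),
                         beta_object = .5, beta_cue = .5,
                         assoc_coeffs = c(.5, 0), max_degree = 2)
  ds2 <- lapply(1:10, function(k)
    simulate_infant(pa, spec_a, d2, seed = 810 + k, sprintf("i%d", k)))
  hb2 <- run_habituation_comparison(ds2, d2, fit_config(seed = 82))
  expect_false(any(hb2$habit_nonzero))
  expect_true(hb2$assoc_nonzero[["a1"]])
  expect_equal(unname(hb2$assoc_median[["a1"]]), 0.5, tolerance = 0.1)
})
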