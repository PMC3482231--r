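test_that("CRP seating probabilities follow the size/concentration formula", {
  expect_equal(crp_assignment_probs(c(3, 1), 1), c(3, 1, 1) / 5)
  expect_equal(crp_assignment_probs(c(2, 2, 2), 2), rep(.25, 4))
  expect_equal(sum(crp_assignment_probs(c(5, 2, 9), 0.7)), 1)
  # vanishing concentration kills the new-table option
  expect_lt(crp_assignment_probs(10, 1e-12)[2], 1e-12)
  expect_error(crp_assignment_probs(c(2, 0), 1), "positive")
  expect_error(crp_assignment_probs(c(2, 1), 0), "positive")
})

test_that("credible intervals are interpolated central quantiles", {
  expect_equal(credible_interval(1:100, .95), c(3.475, 97.525))
  expect_equal(credible_interval(rep(2.5, 10), .68), c(2.5, 2.5))
  s <- rnorm(500)
  ci68 <- credible_interval(s, .68)
  ci95 <- credible_interval(s, .95)
  expect_true(ci95[1] <= ci68[1] && ci68[2] <= ci95[2])
  expect_error(credible_interval(numeric(0), .95), "non-empty")
})

test_that("the buffered non-zero test fires only off the buffer region", {
  expect_false(nonzero_test(rep(0, 50)))
  expect_true(nonzero_test(rep(0.5, 50)))
  set.seed(1)
  expect_false(nonzero_test(runif(2000, -1, 1), level = .95))
  expect_true(nonzero_test(rnorm(2000, mean = .3, sd = .05)))
  expect_false(nonzero_test(rnorm(2000, mean = .0005, sd = 1e-5)))
  expect_error(nonzero_test(numeric(0)))
})

test_that("a lone infant is always reseated at a singleton table", {
  d <- test_only_design(4)
  ds <- list(uniform_gaze(4))
  set.seed(2)
  st <- simple_state(1)
  for (i in 1:20) {
    st <- gibbs_reassign_infant(st, 1, ds, d)
    expect_equal(st$z, 1L)
    expect_length(st$tables, 1)
  }
})

test_that("wildly different infants almost never share a table", {
  d <- build_design("square", 2, 4, seed = 6)
  spec <- model_spec()
  p_a <- cognitive_params(baseline = c(3, -2, -2, -2, -2), max_degree = 2)
  p_b <- cognitive_params(baseline = c(-2, 3, -2, -2, -2), max_degree = 2)
  ds <- list(simulate_infant(p_a, spec, d, seed = 1, "a"),
             simulate_infant(p_b, spec, d, seed = 2, "b"))
  pre <- lapply(ds, gazelink:::precompute_infant, design = d, spec = spec)
  set.seed(3)
  st <- cluster_state(c(1L, 2L),
                      list(gazelink:::params_to_vector(p_a, spec),
                           gazelink:::params_to_vector(p_b, spec)),
                      kappa = 1, sparsity_scales = matrix(1, 2, 6))
  together <- 0
  for (s in 1:100) {
    for (i in 1:2)
      st <- gibbs_reassign_infant(st, i, ds, d, spec, precomp = pre)
    together <- together + (st$z[1] == st$z[2])
  }
  expect_lt(together / 100, 0.05)
})

test_that("a huge concentration drives the prior toward singleton tables", {
  d <- test_only_design(2)
  ds <- lapply(1:8, function(i) uniform_gaze(2, id = i))
  set.seed(4)
  st <- simple_state(8)
  st$kappa <- 1e4
  sizes <- numeric(50)
  for (s in 1:50) {
    for (i in 1:8)
      st <- gibbs_reassign_infant(st, i, ds, d, use_likelihood = FALSE)
    st$kappa <- 1e4
    sizes[s] <- length(st$tables)
  }
  # CRP expectation ~ kappa log(1 + N/kappa) ~ N for huge kappa
  expect_gt(mean(sizes[20:50]), 7)
})

test_that("zero proposal scales leave table parameters unchanged", {
  d <- test_only_design(3)
  ds <- list(uniform_gaze(3))
  st <- simple_state(1)
  cfg <- fit_config(proposal_scales = c(baseline = 0, object = 0, cue = 0,
                                        assoc = 0, habit = 0))
  set.seed(5)
  out <- update_table_params(st, 1, ds, d, cfg)
  expect_equal(out$tables[[1]], st$tables[[1]])
  expect_true(all(attr(out, "accepted"), na.rm = TRUE))
})

test_that("prior-only chains recover the prior (Geweke-style)", {
  d <- test_only_design(2)
  ds <- list(uniform_gaze(2))
  # wide proposals: with the likelihood off the target is the prior itself,
  # whose baseline scale is bl_sd
  cfg <- fit_config(proposal_scales = c(baseline = 2.5, object = 1, cue = 1,
                                        assoc = 1, habit = 1))
  prior <- cfg$prior
  set.seed(6)
  st <- simple_state(1)
  n_iter <- 6000
  draws <- matrix(0, n_iter, 3)  # baseline TL, beta_cue, tau of beta_cue
  for (s in seq_len(n_iter)) {
    st <- update_table_params(st, 1, ds, d, cfg, use_likelihood = FALSE)
    st <- update_hyperparams(st, cfg$model_spec, prior)
    draws[s, ] <- c(st$tables[[1]][1], st$tables[[1]][7],
                    st$sparsity_scales[1, 2])
  }
  # baselines: N(0, bl_sd^2)
  expect_equal(mean(draws[, 1]), 0, tolerance = 0.25)
  expect_equal(sd(draws[, 1]), prior$bl_sd, tolerance = 0.25)
  # local scales: log-uniform on [tau_min, tau_max]
  lt <- log(draws[, 3])
  expect_equal(mean(lt), (log(prior$tau_min) + log(prior$tau_max)) / 2,
               tolerance = 1.2)
  # coefficient marginal: symmetric spike at zero; compare mass near zero
  # and an outer quantile against independent draws from the same prior
  tau_ind <- exp(runif(20000, log(prior$tau_min), log(prior$tau_max)))
  w_ind <- rnorm(20000, 0, sqrt(tau_ind))
  expect_equal(median(draws[, 2]), 0, tolerance = 0.05)
  expect_equal(mean(abs(draws[, 2]) < 0.05), mean(abs(w_ind) < 0.05),
               tolerance = 0.1)
  expect_equal(quantile(draws[, 2], .9), quantile(w_ind, .9),
               tolerance = 0.25, ignore_attr = TRUE)
})

test_that("hyperparameter updates move kappa with the table count", {
  set.seed(7)
  theta <- simple_state(1)$tables[[1]]
  many <- cluster_state(1:10, rep(list(theta), 10), kappa = 1,
                        sparsity_scales = matrix(1, 10, 6))
  one <- cluster_state(rep(1L, 10), list(theta), kappa = 1,
                       sparsity_scales = matrix(1, 1, 6))
  k_many <- replicate(500, update_hyperparams(many)$kappa)
  k_one <- replicate(500, update_hyperparams(one)$kappa)
  expect_gt(mean(k_many), 2 * mean(k_one))
  expect_lt(median(k_one), 1)
})

test_that("the scale of a coefficient pinned at zero stays minimal", {
  set.seed(8)
  st <- simple_state(3)
  st$tables[[1]]["beta_cue"] <- 0
  taus <- replicate(200, update_hyperparams(st)$sparsity_scales[1, 2])
  expect_lt(median(taus), 1e-3)
})

test_that("fitting a single infant always yields one table", {
  d <- build_design("square", 2, 4, seed = 8)
  p <- cognitive_params(beta_object = .5, assoc_coeffs = c(.5, 0),
                        max_degree = 2)
  ds <- list(simulate_infant(p, model_spec(), d, seed = 9))
  ch <- fit_gaze_model(ds, d, fit_config(n_individual_samples = 100,
                                         n_group_samples = 300,
                                         burn_in = 100, seed = 10))
  expect_true(all(ch$n_tables == 1))
  expect_equal(modal_table_count(ch), 1)
})

test_that("fits are bitwise reproducible from the seed", {
  gen <- generate_sim1_dataset(5, 1, seed = 15)
  cfg <- fit_config(n_individual_samples = 100, n_group_samples = 300,
                    burn_in = 100, seed = 16)
  ch1 <- fit_gaze_model(gen$dataset, gen$design, cfg)
  ch2 <- fit_gaze_model(gen$dataset, gen$design, cfg)
  expect_identical(ch1$z, ch2$z)
  expect_identical(ch1$tables, ch2$tables)
  expect_identical(ch1$kappa, ch2$kappa)
})

test_that("fit rejects non-conforming infants before sampling", {
  d <- build_design("square", 2, 4, seed = 1)
  expect_error(fit_gaze_model(list(uniform_gaze(3, "bad")), d), "bad")
})

test_that("a separated two-group dataset recovers both tables", {
  gen <- generate_sim1_dataset(10, 2, seed = 18)
  ch <- fit_gaze_model(gen$dataset, gen$design,
                       fit_config(n_individual_samples = 300,
                                  n_group_samples = 1500, burn_in = 500,
                                  seed = 19))
  expect_equal(modal_table_count(ch), 2)
  expect_lt(misclassification(ch, gen$truth$assignments), 0.05)
})
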