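test_that("looking history is a sound-gated running sum of past rows", {
  d <- test_only_design(4, sounds = c(1L, 2L, 1L, 2L))
  x <- rbind(c(.6, .1, .1, .1, .1),
             c(.3, .2, .2, .2, .1),
             c(.2, .2, .2, .2, .2),
             c(.25, .25, .25, .15, .1))
  h <- compute_history(gaze_matrix("a", x), d)
  # row 1 sees an empty history
  expect_equal(h$H[1, , ], matrix(0, 5, 2), ignore_attr = TRUE)
  expect_equal(h$Hbar[1, ], rep(0, 5), ignore_attr = TRUE)
  # hand summation for AOI TL before trial 4: sound-1 trials gave .6 + .2
  expect_equal(h$H[4, 1, 1], 0.8)
  expect_equal(h$H[4, 1, 2], 0.3)
  expect_equal(unname(h$Hbar[4, 1]), 1.1)
})

test_that("history marginalizes over sounds and is monotone", {
  set.seed(42)
  for (rep in 1:5) {
    d <- build_design("square", 2, 4, seed = rep)
    g <- random_gaze(n_trials(d))
    h <- compute_history(g, d)
    expect_equal(h$H[, , 1] + h$H[, , 2], h$Hbar, ignore_attr = TRUE)
    expect_true(all(diff(h$Hbar) >= -1e-12))
  }
  # all looking in the OTHER AOI leaves the box histories at zero
  d <- test_only_design(3)
  g <- gaze_matrix("o", matrix(rep(c(0, 0, 0, 0, 1), 3), 3, 5, byrow = TRUE))
  h <- compute_history(g, d)
  expect_equal(max(abs(h$H[, 1:4, ])), 0)
})

test_that("history rejects gaze/design length mismatches", {
  d <- test_only_design(3)
  expect_error(compute_history(uniform_gaze(2), d), "rows")
})

test_that("polynomials have no constant term", {
  expect_equal(eval_polynomial(1, 0.5), 0.5)
  expect_equal(eval_polynomial(c(0, 1), 0.5), 0.25)
  expect_equal(eval_polynomial(c(2, -1), 3), -3)
  expect_equal(eval_polynomial(c(1, 1), 0), 0)
})

test_that("concentrations follow the exponentiated linear predictor", {
  d <- build_design("square", 1, 2, seed = 1)
  g <- uniform_gaze(3)
  h <- compute_history(g, d)
  spec <- model_spec()
  p0 <- cognitive_params(max_degree = 2)
  expect_equal(unname(dirichlet_concentrations(p0, spec, d$trials[[1]], h)),
               rep(1, 5))
  # object slope 1 lifts exactly the two object boxes to e
  tr <- d$trials[[1]]
  p_obj <- cognitive_params(beta_object = 1, max_degree = 2)
  a <- dirichlet_concentrations(p_obj, spec, tr, h)
  expect_equal(unname(a), ifelse(tr$objects == 1, exp(1), 1))
  # a cue on one box moves only that box
  tr$cue <- c(0L, 0L, 1L, 0L, 0L)
  p_cue <- cognitive_params(beta_cue = 1, max_degree = 2)
  a <- dirichlet_concentrations(p_cue, spec, tr, h)
  expect_equal(which(abs(a - 1) > 1e-12), c(BL = 3L))
  # predictor overflow names the AOI
  p_big <- cognitive_params(baseline = c(800, 0, 0, 0, 0), max_degree = 2)
  expect_error(dirichlet_concentrations(p_big, spec, tr, h), "TL")
})

test_that("Dirichlet log-density matches closed forms", {
  x <- rep(0.2, 5)
  expect_equal(dirichlet_log_density(x, rep(1, 5)), log(24), tolerance = 1e-9)
  expect_equal(dirichlet_log_density(x, rep(2, 5)),
               lgamma(10) - 5 * lgamma(2) + 5 * log(0.2), tolerance = 1e-9)
  expect_error(dirichlet_log_density(x, c(0, 1, 1, 1, 1)), "positive")
  expect_error(dirichlet_log_density(c(.5, .2, .1, .1, .2), rep(1, 5)),
               "simplex")
})

test_that("Dirichlet density integrates to one on the 2-simplex", {
  # collapse to three categories and integrate the density numerically
  f <- Vectorize(function(x1, x2) {
    x3 <- 1 - x1 - x2
    if (x3 <= 0) return(0)
    exp(dirichlet_log_density(c(x1, x2, x3), c(2.5, 3, 2), 1e-12))
  })
  total <- pracma::integral2(f, 0, 1, 0, function(x) 1 - x,
                             reltol = 1e-10)$Q
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("infant log-likelihood composes the per-trial densities", {
  d <- test_only_design(1)
  spec <- model_spec()
  p0 <- cognitive_params(max_degree = 2)
  expect_equal(log_likelihood_infant(p0, spec, uniform_gaze(1), d), log(24))
  # cross-check the compiled likelihood against the R composition
  set.seed(9)
  d2 <- build_design("face", 2, 4, seed = 9)
  g <- random_gaze(n_trials(d2))
  p <- cognitive_params(baseline = rnorm(5, 0, .5), beta_object = .8,
                        beta_cue = .4, assoc_coeffs = c(.5, -.1),
                        max_degree = 2)
  h <- compute_history(g, d2)
  by_hand <- sum(vapply(seq_len(n_trials(d2)), function(t)
    dirichlet_log_density(g$proportions[t, ],
                          dirichlet_concentrations(p, spec, d2$trials[[t]], h),
                          spec$epsilon_clamp), 0))
  expect_equal(log_likelihood_infant(p, spec, g, d2), by_hand,
               tolerance = 1e-10)
})

test_that("likelihood is permutation-invariant on test-only designs", {
  set.seed(10)
  d <- test_only_design(6, sounds = rep(1:2, 3))
  g <- random_gaze(6)
  spec <- model_spec(include_association = FALSE)
  p <- cognitive_params(baseline = rnorm(5), max_degree = 2)
  perm <- sample(6)
  d_p <- test_only_design(6, sounds = rep(1:2, 3)[perm])
  g_p <- gaze_matrix("r", g$proportions[perm, ])
  expect_equal(log_likelihood_infant(p, spec, g, d),
               log_likelihood_infant(p, spec, g_p, d_p))
})

test_that("history accumulation breaks naive doubling of the likelihood", {
  set.seed(11)
  d <- build_design("square", 1, 2, seed = 4)
  g <- random_gaze(n_trials(d))
  spec <- model_spec()
  p <- cognitive_params(assoc_coeffs = c(1, 0), max_degree = 2)
  ll1 <- log_likelihood_infant(p, spec, g, d)
  # duplicate the session: the second half sees the first half's history
  trials2 <- c(d$trials, lapply(d$trials, function(tr) {
    tr$index <- tr$index + n_trials(d); tr$block <- tr$block + d$n_blocks; tr
  }))
  d2 <- experiment_design(d$condition, trials2, 2 * d$n_blocks,
                          d$n_train_per_block)
  g2 <- gaze_matrix("r", rbind(g$proportions, g$proportions))
  ll2 <- log_likelihood_infant(p, spec, g2, d2)
  expect_gt(abs(ll2 - 2 * ll1), 0.01)
})

test_that("with learning off and zero coefficients the model is a fixed Dirichlet", {
  # baseline differences then recover log-ratios of mean dwell proportions
  set.seed(12)
  base <- c(0.8, 0, -0.4, 0.3, -1)
  p <- cognitive_params(baseline = base, max_degree = 2)
  spec <- model_spec(include_association = FALSE)
  d <- test_only_design(800)
  g <- simulate_infant(p, spec, d, seed = 21)
  m <- colMeans(g$proportions)
  # Dirichlet mean: alpha_i / sum(alpha) = softmax(baseline)
  expect_equal(log(m[1] / m[2]), base[1] - base[2], tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(log(m[4] / m[5]), base[4] - base[5], tolerance = 0.1,
               ignore_attr = TRUE)
})
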