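# Posterior inference: per-infant initialization chains, then a joint
# Metropolis-within-Gibbs chain over CRP cluster assignments, per-cluster
# cognitive parameters under adaptive shrinkage priors, and
# hyperparameters.  The sweep driver lives in C++ (src/sampler.cpp); the
# single-step operations here expose the same moves in R.

#' Prior settings for the linking model
#'
#' Baselines get a fixed zero-mean normal prior (no shrinkage: a baseline
#' of zero is not privileged).  Every other coefficient w gets an
#' adaptive-sparseness prior: w | tau ~ N(0, tau) with a local scale per
#' coefficient and table under a Jeffreys-type hyperprior, p(tau)
#' proportional to 1/tau truncated to `[tau_min, tau_max]` (log-uniform).
#' The 1/tau spike pins coefficients the data do not need at zero —
#' non-contributing factors and superfluous higher-order polynomial terms
#' collapse — while well-supported coefficients are left essentially
#' unshrunk.  The CRP concentration gets a Gamma(kappa_a, kappa_b)
#' hyperprior.
#'
#' @param bl_sd baseline prior standard deviation.
#' @param tau_min,tau_max truncation range of the local scales.
#' @param kappa_a,kappa_b gamma shape and rate for the CRP concentration.
#' @export
default_prior <- function(bl_sd = 2, tau_min = 1e-8, tau_max = 4,
                          kappa_a = 1, kappa_b = 1) {
  list(bl_sd = bl_sd, tau_min = tau_min, tau_max = tau_max,
       kappa_a = kappa_a, kappa_b = kappa_b)
}

#' Sampler configuration
#'
#' @param n_individual_samples length of each per-infant initialization
#'   chain.
#' @param n_group_samples sweeps of the joint group chain.
#' @param burn_in group-chain sweeps discarded (must be < `n_group_samples`);
#'   proposal scales adapt only during burn-in.
#' @param max_degree polynomial degree of the learning functions.
#' @param seed integer seed controlling the whole fit.
#' @param proposal_scales initial random-walk scales per parameter block
#'   (baseline, object, cue, association, habituation).
#' @param ci_buffer region-of-practical-equivalence half-width used by
#'   [nonzero_test()].
#' @param model_spec a [model_spec()].
#' @param m_aux auxiliary tables for the CRP new-table move.
#' @param prior a [default_prior()] list.
#' @export
fit_config <- function(n_individual_samples = 500L, n_group_samples = 3000L,
                       burn_in = 1000L, max_degree = 2L, seed = 1L,
                       proposal_scales = c(baseline = 0.2, object = 0.2,
                                           cue = 0.2, assoc = 0.1,
                                           habit = 0.1),
                       ci_buffer = 0.001,
                       model_spec = gazelink::model_spec(max_degree = max_degree),
                       m_aux = 3L, prior = default_prior()) {
  stopifnot(n_individual_samples >= 1, n_group_samples >= 1,
            burn_in < n_group_samples, length(proposal_scales) == 5)
  structure(list(n_individual_samples = as.integer(n_individual_samples),
                 n_group_samples = as.integer(n_group_samples),
                 burn_in = as.integer(burn_in),
                 max_degree = as.integer(max_degree), seed = as.integer(seed),
                 proposal_scales = proposal_scales, ci_buffer = ci_buffer,
                 model_spec = model_spec, m_aux = as.integer(m_aux),
                 prior = prior),
            class = "fit_config")
}

#' Cluster state of the sampler
#'
#' @param z integer vector of table indices per infant (1-based, no gaps).
#' @param tables list of flat parameter vectors (see [cognitive_params()];
#'   layout baselines, object, cue, association, habituation), one per
#'   occupied table.
#' @param kappa CRP concentration (> 0).
#' @param sparsity_scales matrix of local prior scales tau, one row per
#'   table and one column per non-baseline coefficient.
#' @export
cluster_state <- function(z, tables, kappa, sparsity_scales) {
  z <- as.integer(z)
  sparsity_scales <- as.matrix(sparsity_scales)
  stopifnot(kappa > 0, all(z >= 1), all(z <= length(tables)),
            all(seq_along(tables) %in% z),
            nrow(sparsity_scales) == length(tables),
            all(sparsity_scales > 0))
  structure(list(z = z, tables = tables, kappa = kappa,
                 sparsity_scales = sparsity_scales),
            class = "cluster_state")
}

#' Chinese restaurant process assignment probabilities
#'
#' For occupied-table sizes `n_k` and concentration `kappa`, returns the
#' seating probabilities `n_k / (N + kappa)` for each existing table and
#' `kappa / (N + kappa)` for a new table.
#'
#' @param table_sizes positive integer occupancies of the existing tables.
#' @param kappa positive concentration parameter.
#' @return Probability vector of length `length(table_sizes) + 1`; the
#'   last entry is the new-table probability.
#' @export
crp_assignment_probs <- function(table_sizes, kappa) {
  if (any(table_sizes <= 0)) stop("table sizes must be positive")
  if (kappa <= 0) stop("kappa must be positive")
  p <- c(table_sizes, kappa)
  p / (sum(table_sizes) + kappa)
}

# Internal helpers shared by the R-level steps -----------------------------

spec_toggles <- function(spec) {
  list(D = spec$max_degree, use_cue = spec$include_cue_term,
       use_assoc = spec$include_association,
       use_habit = spec$include_habituation)
}

cpp_cfg <- function(config) {
  spec <- config$model_spec
  pr <- config$prior
  c(spec_toggles(spec),
    list(bl_sd = pr$bl_sd, tau_min = pr$tau_min, tau_max = pr$tau_max,
         kappa_a = pr$kappa_a, kappa_b = pr$kappa_b,
         n_sweeps = config$n_group_samples, burn_in = config$burn_in,
         m_aux = config$m_aux, adapt_interval = 50L,
         scales = unname(config$proposal_scales)))
}

infant_ll <- function(pre_i, theta, spec) {
  tg <- spec_toggles(spec)
  cpp_infant_loglik(pre_i, unname(theta), tg$D, tg$use_cue, tg$use_assoc,
                    tg$use_habit)
}

# Parameter-block index sets (into the flat vector) given the term toggles.
param_blocks <- function(spec) {
  D <- spec$max_degree
  b <- list(baseline = 1:5, object = 6L,
            cue = if (spec$include_cue_term) 7L else integer(0),
            assoc = if (spec$include_association) 7L + seq_len(D) else integer(0),
            habit = if (spec$include_habituation) 7L + D + seq_len(D) else integer(0))
  b
}

# tau index for flat-vector coefficient position j (j >= 6).
tau_index <- function(j) j - 5L

block_log_prior <- function(theta, idx, tau, prior) {
  sds <- ifelse(idx <= 5, prior$bl_sd, sqrt(tau[pmax(tau_index(idx), 1L)]))
  sum(dnorm(theta[idx], 0, sds, log = TRUE))
}

# Joint prior draw of a fresh table: local scales log-uniform on their
# truncated range, then coefficients given the scales.
draw_prior_table_r <- function(spec, prior) {
  D <- spec$max_degree
  tau <- exp(runif(2 + 2 * D, log(prior$tau_min), log(prior$tau_max)))
  theta <- stats::setNames(numeric(7 + 2 * D), param_names(D))
  theta[1:5] <- rnorm(5, 0, prior$bl_sd)
  theta[6] <- rnorm(1, 0, sqrt(tau[1]))
  if (spec$include_cue_term) theta[7] <- rnorm(1, 0, sqrt(tau[2]))
  if (spec$include_association)
    theta[7 + seq_len(D)] <- rnorm(D, 0, sqrt(tau[2 + seq_len(D)]))
  if (spec$include_habituation)
    theta[7 + D + seq_len(D)] <- rnorm(D, 0, sqrt(tau[2 + D + seq_len(D)]))
  list(theta = theta, tau = tau)
}

# Conditional draw of a local scale tau given its coefficient w under the
# truncated Jeffreys-type hyperprior: in x = 1/tau the conditional is
# Gamma(1/2, rate w^2/2) truncated to [1/tau_max, 1/tau_min].
draw_tau_r <- function(w, prior) {
  lo <- 1 / prior$tau_max
  hi <- 1 / prior$tau_min
  w2 <- w^2
  if (w2 < 1e-16) {
    r <- sqrt(lo) + runif(1) * (sqrt(hi) - sqrt(lo))
    return(1 / r^2)
  }
  plo <- pgamma(lo, shape = 0.5, rate = w2 / 2)
  phi <- pgamma(hi, shape = 0.5, rate = w2 / 2)
  x <- if (phi - plo < 1e-14) {
    if (plo > 0.5) lo else hi
  } else {
    qgamma(plo + runif(1) * (phi - plo), shape = 0.5, rate = w2 / 2)
  }
  1 / min(hi, max(lo, x))
}

#' One CRP reassignment move for a single infant
#'
#' Removes the infant from its table (deleting the table if emptied) and
#' reseats it by sampling proportionally to the CRP prior times the
#' infant's likelihood under each table's parameters, with `m_aux` fresh
#' auxiliary tables standing in for the new-table option (Neal's
#' algorithm 8).  A freed table's parameters are recycled as the first
#' auxiliary table.
#'
#' @param state a [cluster_state()].
#' @param infant_index which infant to reseat.
#' @param dataset list of [gaze_matrix()] objects.
#' @param design the shared [experiment_design()].
#' @param spec a [model_spec()].
#' @param prior a [default_prior()].
#' @param m_aux number of auxiliary tables.
#' @param use_likelihood set `FALSE` to sample from the CRP prior alone
#'   (prior predictive checks).
#' @param precomp optional precomputed per-infant matrices (internal).
#' @return The updated [cluster_state()].
#' @export
gibbs_reassign_infant <- function(state, infant_index, dataset, design,
                                  spec = model_spec(), prior = default_prior(),
                                  m_aux = 3L, use_likelihood = TRUE,
                                  precomp = NULL) {
  if (is.null(precomp))
    precomp <- lapply(dataset, precompute_infant, design = design, spec = spec)
  z <- state$z
  tables <- state$tables
  cnt <- tabulate(z, nbins = length(tables))
  old <- z[infant_index]
  cnt[old] <- cnt[old] - 1L
  tau <- state$sparsity_scales
  freed <- NULL
  if (cnt[old] == 0L) {
    freed <- list(theta = tables[[old]], tau = tau[old, ])
    tables[[old]] <- NULL
    tau <- tau[-old, , drop = FALSE]
    cnt <- cnt[-old]
    z[z > old] <- z[z > old] - 1L
  }
  K <- length(tables)
  aux <- lapply(seq_len(m_aux), function(j) {
    if (j == 1 && !is.null(freed)) freed
    else draw_prior_table_r(spec, prior)
  })
  ll <- function(theta) {
    if (use_likelihood) infant_ll(precomp[[infant_index]], theta, spec) else 0
  }
  lw <- c(vapply(seq_len(K), function(k) log(cnt[k]) + ll(tables[[k]]), 0),
          vapply(aux, function(a) log(state$kappa / m_aux) + ll(a$theta), 0))
  w <- exp(lw - max(lw))
  pick <- sample.int(length(w), 1L, prob = w)
  if (pick > K) {
    tables[[K + 1L]] <- aux[[pick - K]]$theta
    tau <- rbind(tau, aux[[pick - K]]$tau)
    z[infant_index] <- K + 1L
  } else {
    z[infant_index] <- pick
  }
  cluster_state(z, tables, state$kappa, tau)
}

#' One Metropolis pass over a table's parameter blocks
#'
#' Random-walk Metropolis updates of each active parameter block
#' (baselines; object slope; cue slope; association coefficients;
#' habituation coefficients) against the product of the member infants'
#' likelihoods and the block's prior.
#'
#' @inheritParams gibbs_reassign_infant
#' @param table_index which table to update.
#' @param config a [fit_config()] (supplies proposal scales, model spec
#'   and prior).
#' @return The updated [cluster_state()], with the per-block acceptance
#'   indicator attached as attribute `"accepted"`.
#' @export
update_table_params <- function(state, table_index, dataset, design,
                                config = fit_config(), use_likelihood = TRUE,
                                precomp = NULL) {
  spec <- config$model_spec
  if (is.null(precomp) && use_likelihood)
    precomp <- lapply(dataset, precompute_infant, design = design, spec = spec)
  members <- which(state$z == table_index)
  if (length(members) == 0) stop("table ", table_index, " is unoccupied")
  theta <- state$tables[[table_index]]
  tau <- state$sparsity_scales[table_index, ]
  blocks <- param_blocks(spec)
  scales <- config$proposal_scales
  mll <- function(th) {
    if (!use_likelihood) return(0)
    sum(vapply(members, function(i) infant_ll(precomp[[i]], th, spec), 0))
  }
  cur <- mll(theta)
  accepted <- stats::setNames(rep(NA, length(blocks)), names(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    if (length(idx) == 0) next
    prop <- theta
    sds <- ifelse(idx <= 5, scales[b],
                  pmin(scales[b], 3 * sqrt(tau[pmax(tau_index(idx), 1L)])))
    prop[idx] <- prop[idx] + sds * rnorm(length(idx))
    lp0 <- block_log_prior(theta, idx, tau, config$prior)
    lp1 <- block_log_prior(prop, idx, tau, config$prior)
    llp <- mll(prop)
    accepted[b] <- log(runif(1)) < (llp + lp1) - (cur + lp0)
    if (accepted[b]) {
      theta <- prop
      cur <- llp
    }
  }
  # exchange move between the collinear learning-function families: per
  # degree, propose a correlated transfer (a_d + t, h_d - r t) with a
  # random ridge ratio r; symmetric under negation, so plain Metropolis.
  if (spec$include_association && spec$include_habituation) {
    D <- spec$max_degree
    exch <- logical(D)
    for (d in seq_len(D)) {
      ja <- 7L + d
      jh <- 7L + D + d
      sdx <- min(scales[4], 3 * sqrt(max(tau[tau_index(ja)],
                                         tau[tau_index(jh)])))
      t_d <- sdx * rnorm(1)
      r <- runif(1, 0.3, 1.2)
      prop <- theta
      prop[ja] <- prop[ja] + t_d
      prop[jh] <- prop[jh] - r * t_d
      idx <- c(ja, jh)
      lp0 <- block_log_prior(theta, idx, tau, config$prior)
      lp1 <- block_log_prior(prop, idx, tau, config$prior)
      llp <- mll(prop)
      exch[d] <- log(runif(1)) < (llp + lp1) - (cur + lp0)
      if (exch[d]) {
        theta <- prop
        cur <- llp
      }
    }
    accepted <- c(accepted, exchange = any(exch))
  }
  state$tables[[table_index]] <- theta
  out <- cluster_state(state$z, state$tables, state$kappa,
                       state$sparsity_scales)
  attr(out, "accepted") <- accepted
  out
}

#' Resample the hyperparameters
#'
#' The local shrinkage scales get their conjugate (truncated-Gamma)
#' update given each table's current coefficient values; the CRP
#' concentration is resampled with the Escobar-West auxiliary-variable
#' scheme under its gamma hyperprior.
#'
#' @inheritParams gibbs_reassign_infant
#' @param n_infants number of customers seated (defaults to
#'   `length(state$z)`).
#' @return The updated [cluster_state()].
#' @export
update_hyperparams <- function(state, spec = model_spec(),
                               prior = default_prior(),
                               n_infants = length(state$z)) {
  K <- length(state$tables)
  tau <- state$sparsity_scales
  blocks <- param_blocks(spec)
  active <- unlist(blocks[c("object", "cue", "assoc", "habit")], use.names = FALSE)
  for (k in seq_len(K)) {
    for (j in active) {
      tau[k, tau_index(j)] <- draw_tau_r(state$tables[[k]][j], prior)
    }
  }
  N <- n_infants
  eta <- rbeta(1, state$kappa + 1, N)
  cc <- prior$kappa_b - log(eta)
  w <- (prior$kappa_a + K - 1) / (N * cc)
  pi_eta <- w / (1 + w)
  kappa <- if (runif(1) < pi_eta) rgamma(1, prior$kappa_a + K, rate = cc)
           else rgamma(1, prior$kappa_a + K - 1, rate = cc)
  cluster_state(state$z, state$tables, min(1e4, max(1e-4, kappa)), tau)
}

# Greedy agglomerative pre-clustering of the stage-1 parameter estimates:
# average-linkage tree, cut at the number of clusters with the best mean
# silhouette (k = 1 unless some k >= 2 clearly separates).
precluster_estimates <- function(est, sil_min = 0.25) {
  n <- nrow(est)
  if (n <= 2) return(rep(1L, n))
  d <- dist(est)
  hc <- hclust(d, method = "average")
  best_k <- 1L
  best_sil <- sil_min
  for (k in 2:min(n - 1L, 8L)) {
    cl <- cutree(hc, k = k)
    sil <- mean(cluster::silhouette(cl, d)[, 3])
    if (sil > best_sil) {
      best_sil <- sil
      best_k <- k
    }
  }
  unname(cutree(hc, k = best_k))
}

#' Fit the linking model to a dataset of infants
#'
#' Two-stage inference.  Stage 1 runs an adaptive random-walk Metropolis
#' chain per infant to obtain rough individual parameter estimates; the
#' estimates are greedily pre-clustered to seed the group tables.  Stage 2
#' runs the joint Metropolis-within-Gibbs chain: every sweep reseats every
#' infant through the CRP (Neal algorithm 8), updates every table's
#' parameter blocks, and resamples the hyperparameters.  The first
#' `burn_in` sweeps are discarded and proposal scales adapt only there.
#'
#' @param dataset list of [gaze_matrix()] objects.
#' @param design the shared [experiment_design()].
#' @param config a [fit_config()].
#' @return A `posterior_chain` with post-burn-in samples: `z` (samples x
#'   infants assignment matrix), `tables` (per-sample table-parameter
#'   matrices), `kappa`, `n_tables`, acceptance rates and the
#'   configuration.
#' @export
fit_gaze_model <- function(dataset, design, config = fit_config()) {
  spec <- config$model_spec
  n <- length(dataset)
  stopifnot(n >= 1)
  for (g in dataset)
    if (nrow(g$proportions) != n_trials(design))
      stop("infant ", g$infant_id, " has ", nrow(g$proportions),
           " rows but the design has ", n_trials(design), " trials")
  set.seed(config$seed)
  pre <- lapply(dataset, precompute_infant, design = design, spec = spec)
  D <- spec$max_degree
  P <- 7L + 2L * D
  cfg <- cpp_cfg(config)

  # Stage 1: per-infant chains; estimates = medians of the second half.
  ns <- config$n_individual_samples
  est <- matrix(0, n, P)
  for (i in seq_len(n)) {
    r <- cpp_individual_chain(pre[[i]], numeric(P), ns, cfg,
                              unname(config$proposal_scales), 1.0)
    keep <- (ns %/% 2 + 1):ns
    est[i, ] <- apply(r$samples[keep, , drop = FALSE], 2, median)
  }

  # Stage 2: greedy pre-clustering seeds the tables, then the group chain.
  z0 <- precluster_estimates(est)
  K0 <- max(z0)
  tables0 <- t(vapply(seq_len(K0), function(k)
    apply(est[z0 == k, , drop = FALSE], 2, median), numeric(P)))
  tau0 <- matrix(1, K0, 2 + 2 * D)
  out <- cpp_group_chain(pre, z0, tables0, 1.0, tau0, cfg)
  structure(list(z = out$z, tables = out$tables, kappa = as.numeric(out$kappa),
                 n_tables = as.integer(out$n_tables),
                 acceptance_rates = stats::setNames(as.numeric(out$accept),
                                                    names(config$proposal_scales)),
                 stage1_estimates = est, config = config,
                 param_names = param_names(D), n_infants = n,
                 infant_ids = vapply(dataset, `[[`, "", "infant_id")),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("<posterior_chain> %d infants, %d post-burn-in samples, modal table count %d\n",
              x$n_infants, nrow(x$z), modal_table_count(x)))
  invisible(x)
}

#' Central credible interval
#'
#' Empirical-quantile interval with mass `mass`, linearly interpolating
#' between order statistics.
#'
#' @param samples numeric vector of posterior draws (non-empty).
#' @param mass interval probability mass in (0, 1).
#' @return Numeric `c(low, high)`.
#' @export
credible_interval <- function(samples, mass = 0.95) {
  if (length(samples) == 0) stop("samples must be non-empty")
  stopifnot(mass > 0, mass < 1)
  unname(quantile(samples, c((1 - mass) / 2, 1 - (1 - mass) / 2),
                  names = FALSE, type = 7))
}

#' Practical non-zero decision for a coefficient
#'
#' `TRUE` iff the central `level` credible interval is disjoint from the
#' buffer region `[-buffer, buffer]` around zero.
#'
#' @param samples posterior draws of the coefficient.
#' @param level credible-interval mass (default .95).
#' @param buffer region-of-practical-equivalence half-width (default .001).
#' @export
nonzero_test <- function(samples, level = 0.95, buffer = 0.001) {
  ci <- credible_interval(samples, level)
  ci[1] > buffer || ci[2] < -buffer
}
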