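# Synthetic infants: the generative direction of the linking model, plus
# the parameter grids and dataset builders used by the recovery studies.

#' Parameter grid for simulated datasets
#'
#' @param object_values,cue_values,assoc_values finite sets of candidate
#'   values for the object slope, cue slope, and first-order association
#'   coefficient.
#' @param baseline_range_onscreen,baseline_range_offscreen uniform sampling
#'   intervals for the four box baselines and the OTHER baseline.
#' @return A `simulation_grid` object.
#' @export
simulation_grid <- function(object_values, cue_values, assoc_values,
                            baseline_range_onscreen = c(-1, 1),
                            baseline_range_offscreen = c(-2, 0)) {
  stopifnot(length(object_values) >= 1, length(cue_values) >= 1,
            length(assoc_values) >= 1,
            diff(baseline_range_onscreen) > 0,
            diff(baseline_range_offscreen) > 0)
  structure(list(object_values = object_values, cue_values = cue_values,
                 assoc_values = assoc_values,
                 baseline_range_onscreen = baseline_range_onscreen,
                 baseline_range_offscreen = baseline_range_offscreen),
            class = "simulation_grid")
}

#' Default grid for the cluster-recovery study (whole steps)
#' @export
sim1_grid <- function() {
  v <- c(0, 0.5, 1.0, 1.5)
  simulation_grid(v, v, v)
}

#' Default grid for the parameter-recovery study (half steps)
#' @export
sim2_grid <- function() {
  v <- seq(0, 1.25, by = 0.25)
  simulation_grid(v, v, v)
}

#' Simulate one infant's gaze matrix
#'
#' Runs the generative model forward: per trial, the looking history is
#' accumulated from the rows already simulated, concentrations are formed
#' from the linear predictor, and one Dirichlet draw becomes the trial's
#' dwell-proportion row.
#'
#' @param params a [cognitive_params()] (the ground truth).
#' @param spec a [model_spec()].
#' @param design an [experiment_design()].
#' @param seed integer seed; identical seeds give identical matrices.
#' @param infant_id identifier for the returned [gaze_matrix()].
#' @export
simulate_infant <- function(params, spec, design, seed, infant_id = "sim") {
  set.seed(seed)
  T_ <- n_trials(design)
  x <- matrix(0, T_, N_AOI)
  acc <- matrix(0, N_AOI, 2L)   # running H by sound
  box <- 1:4
  for (t in seq_len(T_)) {
    tr <- design$trials[[t]]
    eta <- params$baseline
    eta[box] <- eta[box] + params$beta_object * tr$objects[box]
    if (spec$include_cue_term)
      eta[box] <- eta[box] + params$beta_cue * tr$cue[box]
    if (spec$include_association)
      eta[box] <- eta[box] + eval_polynomial(params$assoc_coeffs,
                                             acc[box, tr$sound_id])
    if (spec$include_habituation)
      eta[box] <- eta[box] + eval_polynomial(params$habit_coeffs,
                                             rowSums(acc)[box])
    if (any(abs(eta) > 700))
      stop("linear predictor overflows exp() on simulated trial ", t)
    g <- rgamma(N_AOI, shape = exp(eta), rate = 1)
    while (sum(g) == 0) g <- rgamma(N_AOI, shape = exp(eta), rate = 1)
    x[t, ] <- g / sum(g)
    acc[, tr$sound_id] <- acc[, tr$sound_id] + x[t, ]
  }
  gaze_matrix(infant_id, x)
}

#' Allocate infants to groups
#'
#' Group sizes are drawn from a symmetric multinomial and redrawn until
#' every group is non-empty; the assignment vector lists infants in order.
#'
#' @param n_infants total number of infants (>= `n_groups`).
#' @param n_groups number of groups (>= 1).
#' @param seed integer seed.
#' @return Integer vector of group indices (1-based), length `n_infants`.
#' @export
allocate_groups <- function(n_infants, n_groups, seed) {
  stopifnot(n_groups >= 1, n_infants >= n_groups)
  set.seed(seed)
  repeat {
    counts <- as.vector(rmultinom(1, n_infants, rep(1 / n_groups, n_groups)))
    if (all(counts > 0)) break
  }
  rep(seq_len(n_groups), counts)
}

draw_baselines <- function(grid) {
  c(runif(4, grid$baseline_range_onscreen[1], grid$baseline_range_onscreen[2]),
    runif(1, grid$baseline_range_offscreen[1], grid$baseline_range_offscreen[2]))
}

#' Generate a multi-group dataset for the cluster-recovery study
#'
#' Each group's object slope, cue slope and first-order (linear)
#' association coefficient are drawn *without replacement* from the grid
#' sets, so groups differ in every factor; baselines are drawn uniformly
#' per group.  All infants share one design, and infants are allocated to
#' groups with [allocate_groups()].
#'
#' @param n_infants number of simulated infants.
#' @param n_groups number of true groups (must not exceed the smallest
#'   grid set).
#' @param grid a [simulation_grid()]; defaults to [sim1_grid()].
#' @param seed integer seed.
#' @param condition design condition (default `"square"`, i.e. cued).
#' @return List with `dataset` (list of [gaze_matrix()]), `design`, and
#'   `truth` (`group_params`, `assignments`, `seed`).
#' @export
generate_sim1_dataset <- function(n_infants, n_groups, grid = sim1_grid(),
                                  seed = 1L, condition = "square") {
  small <- min(lengths(grid[c("object_values", "cue_values", "assoc_values")]))
  if (n_groups > small)
    stop("n_groups exceeds the smallest grid set (", small,
         "); without-replacement draws are impossible")
  design <- build_design(condition, 4L, 6L, seed = seed)
  spec <- model_spec()
  set.seed(seed)
  obj <- sample(grid$object_values, n_groups)
  cue <- sample(grid$cue_values, n_groups)
  ass <- sample(grid$assoc_values, n_groups)
  group_params <- lapply(seq_len(n_groups), function(g)
    cognitive_params(baseline = draw_baselines(grid), beta_object = obj[g],
                     beta_cue = cue[g], assoc_coeffs = c(ass[g], 0),
                     max_degree = spec$max_degree))
  assignments <- allocate_groups(n_infants, n_groups, seed + 1L)
  set.seed(seed + 2L)
  infant_seeds <- sample.int(.Machine$integer.max - 1L, n_infants)
  dataset <- lapply(seq_len(n_infants), function(i)
    simulate_infant(group_params[[assignments[i]]], spec, design,
                    seed = infant_seeds[i], infant_id = sprintf("infant%02d", i)))
  list(dataset = dataset, design = design,
       truth = list(group_params = group_params, assignments = assignments,
                    seed = seed))
}

# Association-polynomial templates for the learning-function study.  The
# U-shaped turning points fall inside the history range reachable in a
# 28-trial session.
SIM3_TEMPLATES <- list(linear_up = c(0.35, 0), linear_down = c(-0.35, 0),
                       u_up = c(-0.6, 0.15), u_down = c(0.6, -0.15))

#' Generate a single-group dataset with a chosen learning-function shape
#'
#' The association coefficients follow the named template (linear kinds
#' have a zero quadratic term; U-shaped kinds a non-zero one); the object
#' and cue slopes are drawn with replacement from the grid and baselines
#' uniformly from their ranges, once per run.
#'
#' @param function_kind one of `"linear_up"`, `"linear_down"`, `"u_up"`,
#'   `"u_down"`.
#' @param n_infants infants per run (all in one group).
#' @param grid a [simulation_grid()]; defaults to [sim2_grid()].
#' @param seed integer seed.
#' @return Same shape as [generate_sim1_dataset()].
#' @export
generate_sim3_dataset <- function(function_kind, n_infants = 10L,
                                  grid = sim2_grid(), seed = 1L) {
  if (!function_kind %in% names(SIM3_TEMPLATES))
    stop("unknown learning-function kind: ", function_kind)
  design <- build_design("square", 4L, 6L, seed = seed)
  spec <- model_spec()
  set.seed(seed)
  params <- cognitive_params(baseline = draw_baselines(grid),
                             beta_object = sample(grid$object_values, 1),
                             beta_cue = sample(grid$cue_values, 1),
                             assoc_coeffs = SIM3_TEMPLATES[[function_kind]],
                             max_degree = spec$max_degree)
  set.seed(seed + 2L)
  infant_seeds <- sample.int(.Machine$integer.max - 1L, n_infants)
  dataset <- lapply(seq_len(n_infants), function(i)
    simulate_infant(params, spec, design, seed = infant_seeds[i],
                    infant_id = sprintf("infant%02d", i)))
  list(dataset = dataset, design = design,
       truth = list(group_params = list(params),
                    assignments = rep(1L, n_infants), seed = seed,
                    function_kind = function_kind))
}
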