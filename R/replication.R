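# End-to-end recovery studies: cluster-count recovery, factorial parameter
# recovery, learning-function shape discrimination, the
# habituation-vs-association comparison, and the no-cue regularization
# check.  Each run derives its seed from the configuration seed, so a
# whole sweep reproduces from one number.

run_seed <- function(base, i, j = 0L) {
  (as.integer(base) + 7919L * as.integer(i) + 104729L * as.integer(j)) %%
    .Machine$integer.max
}

#' Cluster-count recovery study
#'
#' For each group size: repeatedly generate a multi-group dataset
#' ([generate_sim1_dataset()]), fit it, and score the modal table count
#' and the sample-wise misclassification against the ground truth.
#'
#' @param group_sizes true group counts to test.
#' @param runs_per_size independent datasets per group size.
#' @param n_infants infants per dataset.
#' @param config a [fit_config()]; its seed drives the whole sweep.
#' @param grid parameter grid (default [sim1_grid()]).
#' @return List with `summary` (per size: correct-count rate, mean
#'   misclassification overall and on correct-count runs) and `runs`
#'   (per-run details including seeds).
#' @export
run_simulation1 <- function(group_sizes = 1:3, runs_per_size = 5L,
                            n_infants = 12L, config = fit_config(),
                            grid = sim1_grid()) {
  runs <- list()
  for (size in group_sizes) {
    for (r in seq_len(runs_per_size)) {
      seed <- run_seed(config$seed, size, r)
      gen <- generate_sim1_dataset(n_infants, size, grid, seed = seed)
      cfg <- config
      cfg$seed <- seed + 1L
      chain <- fit_gaze_model(gen$dataset, gen$design, cfg)
      runs[[length(runs) + 1L]] <- data.frame(
        n_groups = size, run = r, seed = seed,
        modal_tables = modal_table_count(chain),
        misclassification = misclassification(chain, gen$truth$assignments))
    }
  }
  if (length(runs) == 0) {
    empty <- data.frame(n_groups = integer(0), correct_count_rate = numeric(0),
                        mean_misclassification = numeric(0),
                        mean_misclassification_correct = numeric(0))
    return(list(summary = empty, runs = empty[0, ]))
  }
  runs <- do.call(rbind, runs)
  runs$correct <- runs$modal_tables == runs$n_groups
  summary <- do.call(rbind, lapply(split(runs, runs$n_groups), function(d)
    data.frame(n_groups = d$n_groups[1],
               correct_count_rate = mean(d$correct),
               mean_misclassification = mean(d$misclassification),
               mean_misclassification_correct =
                 if (any(d$correct)) mean(d$misclassification[d$correct]) else NA_real_)))
  rownames(summary) <- NULL
  list(summary = summary, runs = runs)
}

default_sim2_cells <- function(grid) {
  v <- function(set) set[c(1, 3, 5)]
  expand.grid(object = v(grid$object_values), cue = v(grid$cue_values),
              assoc = v(grid$assoc_values))
}

#' Factorial parameter-recovery study
#'
#' Simulates one single-group dataset per cell of a (sub)factorial over
#' object, cue and linear-association values, fits each, and regresses
#' the inferred posterior medians (largest consensus cluster) on the
#' truth, factor by factor.
#'
#' @param cells data frame with columns `object`, `cue`, `assoc`; defaults
#'   to a 27-cell subsample of the factorial (every other grid value).
#' @param n_infants infants per cell (one group).
#' @param config a [fit_config()].
#' @param grid parameter grid (default [sim2_grid()], half steps).
#' @return List with `recovery` (per cell: true and inferred values plus
#'   practical non-zero verdicts) and `stats` (per factor: regression
#'   slope, intercept, R^2).
#' @export
run_simulation2 <- function(cells = NULL, n_infants = 10L,
                            config = fit_config(), grid = sim2_grid()) {
  if (is.null(cells)) cells <- default_sim2_cells(grid)
  spec <- config$model_spec
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    seed <- run_seed(config$seed, i, 53L)
    set.seed(seed)
    params <- cognitive_params(baseline = draw_baselines(grid),
                               beta_object = cells$object[i],
                               beta_cue = cells$cue[i],
                               assoc_coeffs = c(cells$assoc[i], 0),
                               max_degree = spec$max_degree)
    design <- build_design("square", 4L, 6L, seed = seed)
    infant_seeds <- sample.int(.Machine$integer.max - 1L, n_infants)
    dataset <- lapply(seq_len(n_infants), function(k)
      simulate_infant(params, spec, design, seed = infant_seeds[k],
                      infant_id = sprintf("infant%02d", k)))
    cfg <- config
    cfg$seed <- seed + 1L
    chain <- fit_gaze_model(dataset, design, cfg)
    cs <- consensus_partition(chain)
    main <- which.max(cs$occupancy)
    med <- cs$param_median[main, ]
    nz <- function(p) nonzero_test(cluster_param_samples(cs, p, main),
                                   buffer = config$ci_buffer)
    rows[[i]] <- data.frame(
      cell = i, seed = seed,
      object_true = cells$object[i], object_est = med[["beta_object"]],
      object_nonzero = nz("beta_object"),
      cue_true = cells$cue[i], cue_est = med[["beta_cue"]],
      cue_nonzero = nz("beta_cue"),
      assoc_true = cells$assoc[i], assoc_est = med[["a1"]],
      assoc_nonzero = nz("a1"))
  }
  recovery <- do.call(rbind, rows)
  stats <- do.call(rbind, lapply(c("object", "cue", "assoc"), function(f) {
    m <- lm(recovery[[paste0(f, "_est")]] ~ recovery[[paste0(f, "_true")]])
    data.frame(factor = f, slope = unname(coef(m)[2]),
               intercept = unname(coef(m)[1]),
               r_squared = summary(m)$r.squared)
  }))
  list(recovery = recovery, stats = stats)
}

#' Learning-function discrimination study
#'
#' Generates single-group datasets under each learning-function template
#' ([generate_sim3_dataset()]), fits each, and applies the buffered 95%
#' credible-interval non-zero test to the linear and quadratic association
#' coefficients of the main consensus cluster.
#'
#' @param kinds learning-function kinds to test.
#' @param runs_per_kind independent runs per kind.
#' @param n_infants infants per run.
#' @param config a [fit_config()].
#' @param grid parameter grid (default [sim2_grid()]).
#' @return List with `summary` (per kind: proportion of runs with nonzero
#'   linear and quadratic terms), `runs` (per-run verdicts), and
#'   `linear_type2_rate` (runs whose truly nonzero linear term tested
#'   zero).
#' @export
run_simulation3 <- function(kinds = names(SIM3_TEMPLATES), runs_per_kind = 5L,
                            n_infants = 10L, config = fit_config(),
                            grid = sim2_grid()) {
  rows <- list()
  for (ki in seq_along(kinds)) {
    for (r in seq_len(runs_per_kind)) {
      seed <- run_seed(config$seed, ki, 997L + r)
      gen <- generate_sim3_dataset(kinds[ki], n_infants, grid, seed = seed)
      cfg <- config
      cfg$seed <- seed + 1L
      chain <- fit_gaze_model(gen$dataset, gen$design, cfg)
      cs <- consensus_partition(chain)
      main <- which.max(cs$occupancy)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kinds[ki], run = r, seed = seed,
        a1_nonzero = nonzero_test(cluster_param_samples(cs, "a1", main),
                                  buffer = config$ci_buffer),
        a2_nonzero = nonzero_test(cluster_param_samples(cs, "a2", main),
                                  buffer = config$ci_buffer),
        a1_median = cs$param_median[main, "a1"],
        a2_median = cs$param_median[main, "a2"])
    }
  }
  runs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(runs, runs$kind), function(d)
    data.frame(kind = d$kind[1], prop_a1_nonzero = mean(d$a1_nonzero),
               prop_a2_nonzero = mean(d$a2_nonzero))))
  rownames(summary) <- NULL
  truly_linear <- vapply(as.character(runs$kind),
                         function(k) SIM3_TEMPLATES[[k]][1] != 0, TRUE)
  list(summary = summary, runs = runs,
       linear_type2_rate = mean(!runs$a1_nonzero[truly_linear]))
}

#' Habituation-vs-association model comparison on one dataset
#'
#' Fits the model with both learning-function families enabled and
#' reports the buffered non-zero verdict for every association and
#' habituation coefficient of the main consensus cluster.
#'
#' @param dataset list of [gaze_matrix()] objects.
#' @param design the shared [experiment_design()].
#' @param config a [fit_config()]; its model spec is overridden to enable
#'   both families.
#' @return List with logical vectors `assoc_nonzero`, `habit_nonzero`,
#'   the matching medians, and the fitted chain.
#' @export
run_habituation_comparison <- function(dataset, design,
                                       config = fit_config()) {
  spec <- config$model_spec
  spec$include_association <- TRUE
  spec$include_habituation <- TRUE
  config$model_spec <- spec
  chain <- fit_gaze_model(dataset, design, config)
  cs <- consensus_partition(chain)
  main <- which.max(cs$occupancy)
  D <- spec$max_degree
  verdict <- function(p) nonzero_test(cluster_param_samples(cs, p, main),
                                      buffer = config$ci_buffer)
  a_names <- paste0("a", seq_len(D))
  h_names <- paste0("h", seq_len(D))
  list(assoc_nonzero = vapply(a_names, verdict, TRUE),
       habit_nonzero = vapply(h_names, verdict, TRUE),
       assoc_median = cs$param_median[main, a_names],
       habit_median = cs$param_median[main, h_names],
       chain = chain)
}

#' No-cue regularization check
#'
#' Simulates datasets in the no-cue condition (cue indicator identically
#' zero, true cue coefficient zero) while keeping the cue term in the
#' fitted model, and checks that its posterior stays pinned at zero: the
#' shrinkage prior should absorb the non-contributing parameter.
#'
#' @param n_runs independent datasets.
#' @param n_infants infants per dataset (one group).
#' @param config a [fit_config()].
#' @param grid parameter grid for the other factors (default [sim1_grid()]).
#' @return Data frame per run: posterior median of the cue coefficient
#'   (main cluster) and its non-zero verdict.
#' @export
run_nocue_regularization <- function(n_runs = 10L, n_infants = 12L,
                                     config = fit_config(),
                                     grid = sim1_grid()) {
  spec <- config$model_spec
  rows <- list()
  for (r in seq_len(n_runs)) {
    seed <- run_seed(config$seed, r, 31L)
    design <- build_design("no_cue", 4L, 6L, seed = seed)
    set.seed(seed)
    params <- cognitive_params(baseline = draw_baselines(grid),
                               beta_object = sample(grid$object_values, 1),
                               beta_cue = 0,
                               assoc_coeffs = c(sample(grid$assoc_values, 1), 0),
                               max_degree = spec$max_degree)
    infant_seeds <- sample.int(.Machine$integer.max - 1L, n_infants)
    dataset <- lapply(seq_len(n_infants), function(k)
      simulate_infant(params, spec, design, seed = infant_seeds[k],
                      infant_id = sprintf("infant%02d", k)))
    cfg <- config
    cfg$seed <- seed + 1L
    chain <- fit_gaze_model(dataset, design, cfg)
    cs <- consensus_partition(chain)
    main <- which.max(cs$occupancy)
    rows[[r]] <- data.frame(
      run = r, seed = seed,
      beta_cue_median = cs$param_median[main, "beta_cue"],
      beta_cue_nonzero = nonzero_test(cluster_param_samples(cs, "beta_cue", main),
                                      buffer = config$ci_buffer))
  }
  do.call(rbind, rows)
}
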