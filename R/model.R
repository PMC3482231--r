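# The generative model: cumulative sound-contingent looking history,
# polynomial association and habituation functions of that history, an
# exponentiated linear predictor per AOI, and a Dirichlet outcome
# distribution over per-trial dwell proportions.

#' Observed dwell-proportion matrix for one infant
#'
#' @param infant_id identifier string.
#' @param proportions T x 5 matrix of dwell-time proportions, one row per
#'   trial in design order, columns TL, TR, BL, BR, OTHER.  Rows must sum
#'   to 1 (tolerance `1e-9`) and entries must be non-negative.
#' @return A `gaze_matrix` object.
#' @export
gaze_matrix <- function(infant_id, proportions) {
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != N_AOI)
    stop("gaze matrix must have exactly ", N_AOI, " columns")
  if (any(proportions < 0))
    stop("dwell proportions must be non-negative")
  if (any(abs(rowSums(proportions) - 1) > 1e-9))
    stop("every row of a gaze matrix must sum to 1")
  colnames(proportions) <- AOI_NAMES
  structure(list(infant_id = as.character(infant_id),
                 proportions = proportions),
            class = "gaze_matrix")
}

#' @export
print.gaze_matrix <- function(x, ...) {
  cat(sprintf("<gaze_matrix> infant %s, %d trials x %d AOIs\n",
              x$infant_id, nrow(x$proportions), ncol(x$proportions)))
  invisible(x)
}

#' Cognitive parameters of the linking model
#'
#' @param baseline length-5 vector of per-AOI preference constants.
#' @param beta_object slope on the object-presence indicator.
#' @param beta_cue slope on the cue indicator.
#' @param assoc_coeffs polynomial coefficients (degree 1..D, no constant
#'   term) of the association function of sound-contingent looking history.
#' @param habit_coeffs polynomial coefficients of the habituation function
#'   of sound-independent looking history; all zero disables habituation.
#' @param max_degree polynomial degree D; coefficient vectors are padded
#'   with zeros to this length.
#' @return A `cognitive_params` object.
#' @export
cognitive_params <- function(baseline = numeric(N_AOI), beta_object = 0,
                             beta_cue = 0, assoc_coeffs = 0,
                             habit_coeffs = 0, max_degree = 2L) {
  max_degree <- as.integer(max_degree)
  stopifnot(length(baseline) == N_AOI, max_degree >= 1,
            length(assoc_coeffs) <= max_degree,
            length(habit_coeffs) <= max_degree)
  pad <- function(v) c(v, numeric(max_degree - length(v)))
  p <- structure(list(baseline = as.numeric(baseline),
                      beta_object = as.numeric(beta_object),
                      beta_cue = as.numeric(beta_cue),
                      assoc_coeffs = pad(as.numeric(assoc_coeffs)),
                      habit_coeffs = pad(as.numeric(habit_coeffs)),
                      max_degree = max_degree),
                 class = "cognitive_params")
  if (!all(is.finite(unlist(p[1:5])))) stop("all parameters must be finite")
  p
}

#' Model-term toggles and numerical settings
#'
#' @param include_cue_term include the cue slope in the predictor (kept on
#'   even in no-cue designs, where its indicator is all zero, as a
#'   regularization check).
#' @param include_association include the association polynomial.
#' @param include_habituation include the habituation polynomial.
#' @param max_degree polynomial degree D of both learning functions.
#' @param epsilon_clamp boundary smoothing for observed proportions; rows
#'   are clamped to `[epsilon_clamp, 1 - epsilon_clamp]` and renormalized
#'   before evaluating the Dirichlet density.
#' @return A `model_spec` object.
#' @export
model_spec <- function(include_cue_term = TRUE, include_association = TRUE,
                       include_habituation = FALSE, max_degree = 2L,
                       epsilon_clamp = 1e-12) {
  stopifnot(max_degree >= 1, epsilon_clamp > 0, epsilon_clamp < 0.01)
  structure(list(include_cue_term = include_cue_term,
                 include_association = include_association,
                 include_habituation = include_habituation,
                 max_degree = as.integer(max_degree),
                 epsilon_clamp = epsilon_clamp),
            class = "model_spec")
}

#' Cumulative looking history
#'
#' For each trial t, AOI i and sound s, `H[t, i, s]` is the infant's
#' cumulative dwell proportion in AOI i summed over the trials strictly
#' before t on which sound s played (a Kronecker-delta-gated running sum);
#' `Hbar[t, i]` is the same sum regardless of sound.  Row 1 is all zero.
#'
#' @param gaze a [gaze_matrix()].
#' @param design the matching [experiment_design()].
#' @param average if `TRUE`, divide each entry by the number of qualifying
#'   past trials instead of leaving a running sum (default `FALSE`).
#' @return A `looking_history` list with elements `H` (T x 5 x 2 array) and
#'   `Hbar` (T x 5 matrix).
#' @export
compute_history <- function(gaze, design, average = FALSE) {
  x <- gaze$proportions
  T_ <- nrow(x)
  if (T_ != n_trials(design))
    stop("gaze matrix has ", T_, " rows but the design has ",
         n_trials(design), " trials")
  sound <- vapply(design$trials, `[[`, 0L, "sound_id")
  H <- array(0, dim = c(T_, N_AOI, 2L),
             dimnames = list(NULL, AOI_NAMES, c("sound1", "sound2")))
  Hbar <- matrix(0, T_, N_AOI, dimnames = list(NULL, AOI_NAMES))
  acc <- matrix(0, N_AOI, 2L)
  cnt <- c(0L, 0L)
  for (t in seq_len(T_)) {
    if (average) {
      H[t, , 1L] <- if (cnt[1L] > 0) acc[, 1L] / cnt[1L] else 0
      H[t, , 2L] <- if (cnt[2L] > 0) acc[, 2L] / cnt[2L] else 0
      Hbar[t, ] <- if (t > 1) rowSums(acc) / (t - 1) else 0
    } else {
      H[t, , ] <- acc
      Hbar[t, ] <- rowSums(acc)
    }
    s <- sound[t]
    acc[, s] <- acc[, s] + x[t, ]
    cnt[s] <- cnt[s] + 1L
  }
  structure(list(H = H, Hbar = Hbar, average = average),
            class = "looking_history")
}

#' Evaluate a zero-intercept polynomial
#'
#' Returns `sum(coeffs[d] * x^d)` for d = 1..D.  There is no constant
#' term: the per-AOI baseline already plays that role.
#'
#' @param coeffs coefficients of degrees 1..D.
#' @param x evaluation point(s).
#' @export
eval_polynomial <- function(coeffs, x) {
  stopifnot(all(is.finite(x)))
  out <- 0
  xp <- x
  for (d in seq_along(coeffs)) {
    out <- out + coeffs[d] * xp
    xp <- xp * x
  }
  out
}

#' Dirichlet concentrations for one trial
#'
#' Forms the linear predictor per AOI — baseline, plus object and cue
#' slopes times their indicators, plus the association polynomial of the
#' sound-contingent looking history and (optionally) the habituation
#' polynomial of the sound-independent history — and exponentiates it.
#' The learning terms apply only to the four boxes; the OTHER AOI carries
#' its baseline alone.
#'
#' @param params a [cognitive_params()].
#' @param spec a [model_spec()].
#' @param trial a [trial_spec()]; its `index` selects the history row.
#' @param history a [compute_history()] result covering the trial.
#' @return Positive length-5 concentration vector.
#' @export
dirichlet_concentrations <- function(params, spec, trial, history) {
  t <- trial$index
  if (t > nrow(history$Hbar)) stop("history does not cover trial ", t)
  eta <- params$baseline
  box <- 1:4
  eta[box] <- eta[box] + params$beta_object * trial$objects[box]
  if (spec$include_cue_term)
    eta[box] <- eta[box] + params$beta_cue * trial$cue[box]
  if (spec$include_association)
    eta[box] <- eta[box] +
      eval_polynomial(params$assoc_coeffs, history$H[t, box, trial$sound_id])
  if (spec$include_habituation)
    eta[box] <- eta[box] +
      eval_polynomial(params$habit_coeffs, history$Hbar[t, box])
  if (any(abs(eta) > 700))
    stop("linear predictor overflows exp() at AOI ",
         AOI_NAMES[which.max(abs(eta))], " (trial ", t, ")")
  stats::setNames(exp(eta), AOI_NAMES)
}

#' Dirichlet log-density with boundary clamping
#'
#' Clamps each observed proportion into `[epsilon_clamp, 1 - epsilon_clamp]`,
#' renormalizes the row, and evaluates
#' `log Gamma(sum(alpha)) - sum(log Gamma(alpha)) + sum((alpha - 1) log x)`.
#'
#' @param x_row proportion vector on the simplex (length >= 2; the model
#'   uses length 5).
#' @param alpha positive concentration vector of the same length.
#' @param epsilon_clamp boundary clamp (see [model_spec()]).
#' @return Log density (a real number).
#' @export
dirichlet_log_density <- function(x_row, alpha, epsilon_clamp = 1e-12) {
  if (length(x_row) != length(alpha) || length(x_row) < 2)
    stop("x_row and alpha must have equal length >= 2")
  if (any(alpha <= 0)) stop("Dirichlet concentrations must be positive")
  if (abs(sum(x_row) - 1) > 1e-6)
    stop("x_row is off the simplex: sum = ", format(sum(x_row)))
  x <- pmin(pmax(x_row, epsilon_clamp), 1 - epsilon_clamp)
  x <- x / sum(x)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

#' Log-likelihood of one infant's full gaze matrix
#'
#' Sums the trial-wise Dirichlet log-density over the session, with the
#' looking history computed from the infant's own observed gaze (the model
#' conditions on the infant's actual past looking).
#'
#' @param params a [cognitive_params()].
#' @param spec a [model_spec()].
#' @param gaze a [gaze_matrix()].
#' @param design the matching [experiment_design()].
#' @export
log_likelihood_infant <- function(params, spec, gaze, design) {
  pre <- precompute_infant(gaze, design, spec)
  cpp_infant_loglik(pre, params_to_vector(params, spec), spec$max_degree,
                    spec$include_cue_term, spec$include_association,
                    spec$include_habituation)
}

# --- flat parameter vector layout shared with the C++ sampler -------------
# [1:5] baselines, [6] beta_object, [7] beta_cue, [8:(7+D)] assoc, then habit.

param_names <- function(D) {
  c(paste0("b_", AOI_NAMES), "beta_object", "beta_cue",
    paste0("a", seq_len(D)), paste0("h", seq_len(D)))
}

params_to_vector <- function(params, spec) {
  D <- spec$max_degree
  stopifnot(params$max_degree == D)
  stats::setNames(c(params$baseline, params$beta_object, params$beta_cue,
                    params$assoc_coeffs, params$habit_coeffs),
                  param_names(D))
}

vector_to_params <- function(theta, D) {
  cognitive_params(baseline = theta[1:5], beta_object = theta[6],
                   beta_cue = theta[7], assoc_coeffs = theta[8:(7 + D)],
                   habit_coeffs = theta[(8 + D):(7 + 2 * D)],
                   max_degree = D)
}

# Precompute the per-infant matrices the likelihood needs: clamped log
# proportions, object/cue indicators, and the history evaluated at each
# trial's sound (Hs) and marginally (Hbar).
precompute_infant <- function(gaze, design, spec) {
  x <- gaze$proportions
  hist <- compute_history(gaze, design)
  dm <- design_matrices(design)
  T_ <- nrow(x)
  Hs <- matrix(0, T_, N_AOI)
  for (t in seq_len(T_)) Hs[t, ] <- hist$H[t, , dm$sound[t]]
  xc <- pmin(pmax(x, spec$epsilon_clamp), 1 - spec$epsilon_clamp)
  xc <- xc / rowSums(xc)
  list(logx = log(xc), obj = dm$objects * 1.0, cue = dm$cue * 1.0,
       Hs = Hs, Hbar = hist$Hbar)
}
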