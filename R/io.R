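# Readers and writers for the package's plain-text formats: long-format
# gaze CSV, design JSON (see design.R), ground-truth JSON and chain CSVs.

#' Write a gaze dataset to long-format CSV
#'
#' Columns: `infant_id`, `trial_index`, `aoi` (TL/TR/BL/BR/OTHER),
#' `proportion`.
#'
#' @param dataset list of [gaze_matrix()] objects.
#' @param path output file.
#' @export
write_gaze_csv <- function(dataset, path) {
  rows <- do.call(rbind, lapply(dataset, function(g) {
    T_ <- nrow(g$proportions)
    data.frame(infant_id = g$infant_id,
               trial_index = rep(seq_len(T_), each = N_AOI),
               aoi = rep(AOI_NAMES, T_),
               proportion = as.vector(t(g$proportions)))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gaze dataset from long-format CSV
#'
#' Accepts AOI labels as names (TL/TR/BL/BR/OTHER) or indices 0-4.  Each
#' trial's proportions must close to 1: rows off by at most `1e-3` are
#' renormalized, larger violations raise an error naming the infant and
#' trial.
#'
#' @param path file written by [write_gaze_csv()] (or equivalent).
#' @param design optional [experiment_design()]; if given, every infant
#'   must cover exactly its trials.
#' @return List of [gaze_matrix()] objects, in file order of first
#'   appearance.
#' @export
read_gaze_csv <- function(path, design = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("infant_id", "trial_index", "aoi", "proportion")
  if (!all(need %in% names(df)))
    stop("gaze CSV must have columns ", paste(need, collapse = ", "))
  aoi <- as.character(df$aoi)
  idx <- match(aoi, AOI_NAMES)
  numeric_aoi <- suppressWarnings(as.integer(aoi))
  idx[is.na(idx)] <- numeric_aoi[is.na(idx)] + 1L
  if (any(is.na(idx)) || any(idx < 1 | idx > N_AOI))
    stop("unrecognized AOI labels in ", path)
  df$aoi_idx <- idx
  ids <- unique(df$infant_id)
  lapply(ids, function(id) {
    d <- df[df$infant_id == id, ]
    trials <- sort(unique(d$trial_index))
    if (!identical(trials, seq_along(trials)))
      stop("infant ", id, ": trial indices must be 1..T without gaps")
    if (!is.null(design) && length(trials) != n_trials(design))
      stop("infant ", id, " has ", length(trials),
           " trials but the design has ", n_trials(design))
    x <- matrix(NA_real_, length(trials), N_AOI)
    x[cbind(d$trial_index, d$aoi_idx)] <- d$proportion
    if (anyNA(x)) stop("infant ", id, ": missing AOI proportions")
    for (t in seq_len(nrow(x))) {
      s <- sum(x[t, ])
      if (abs(s - 1) > 1e-3)
        stop("infant ", id, " trial ", t, ": proportions sum to ",
             format(s), ", beyond tolerance 1e-3")
      x[t, ] <- x[t, ] / s
    }
    gaze_matrix(id, x)
  })
}

#' Write ground truth to JSON
#' @param truth the `truth` element of a generated dataset.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(groups = lapply(truth$group_params, function(p)
    list(baseline = p$baseline, beta_object = p$beta_object,
         beta_cue = p$beta_cue, assoc_coeffs = p$assoc_coeffs,
         habit_coeffs = p$habit_coeffs, max_degree = p$max_degree)),
    assignments = truth$assignments, seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth from JSON
#' @param path file written by [write_truth_json()].
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- if (is.data.frame(obj$groups)) {
    lapply(seq_len(nrow(obj$groups)), function(i)
      cognitive_params(baseline = obj$groups$baseline[[i]],
                       beta_object = obj$groups$beta_object[i],
                       beta_cue = obj$groups$beta_cue[i],
                       assoc_coeffs = obj$groups$assoc_coeffs[[i]],
                       habit_coeffs = obj$groups$habit_coeffs[[i]],
                       max_degree = obj$groups$max_degree[i]))
  } else {
    lapply(obj$groups, function(g)
      cognitive_params(baseline = g$baseline, beta_object = g$beta_object,
                       beta_cue = g$beta_cue, assoc_coeffs = g$assoc_coeffs,
                       habit_coeffs = g$habit_coeffs,
                       max_degree = g$max_degree))
  }
  list(group_params = groups, assignments = as.integer(obj$assignments),
       seed = obj$seed)
}

#' Write a posterior chain to CSV files
#'
#' Writes `assignments.csv` (sample x infant table indices),
#' `table_params.csv` (long format: sample, table, parameter, value) and
#' `config.json` into `dir`.
#'
#' @param chain a `posterior_chain`.
#' @param dir output directory (created if missing).
#' @export
write_chain_csv <- function(chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- as.data.frame(chain$z)
  names(z) <- chain$infant_ids
  z <- cbind(sample = seq_len(nrow(z)), z)
  write.csv(z, file.path(dir, "assignments.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(seq_along(chain$tables), function(s) {
    tab <- chain$tables[[s]]
    data.frame(sample = s, table = rep(seq_len(nrow(tab)), ncol(tab)),
               parameter = rep(chain$param_names, each = nrow(tab)),
               value = as.vector(tab))
  }))
  write.csv(long, file.path(dir, "table_params.csv"), row.names = FALSE)
  cfg <- chain$config
  cfg$model_spec <- unclass(cfg$model_spec)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
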