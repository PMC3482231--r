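# Encoding of the cued multi-modal learning paradigm: blocks of training
# trials (objects in one of two diagonal box pairs, each pair bound to a
# unique sound, optionally one cued box) each followed by a sound-only test
# trial.

#' Create a single trial specification
#'
#' @param index 1-based position of the trial in the session.
#' @param block 1-based block number.
#' @param kind `"training"` or `"test"`.
#' @param sound_id which of the two sounds plays (1 or 2).
#' @param objects binary length-5 vector of object presence per AOI.
#' @param cue binary length-5 vector of cue presence per AOI.
#' @return A `trial_spec` list.
#' @export
trial_spec <- function(index, block, kind, sound_id, objects, cue) {
  kind <- match.arg(kind, c("training", "test"))
  stopifnot(length(objects) == N_AOI, length(cue) == N_AOI,
            all(objects %in% c(0, 1)), all(cue %in% c(0, 1)),
            sound_id %in% c(1L, 2L))
  structure(list(index = as.integer(index), block = as.integer(block),
                 kind = kind, sound_id = as.integer(sound_id),
                 objects = as.integer(objects), cue = as.integer(cue)),
            class = "trial_spec")
}

#' Create an experiment design from a list of trials
#'
#' Light constructor; use [validate_design()] to check the invariants.
#'
#' @param condition `"face"`, `"square"` or `"no_cue"`.
#' @param trials list of [trial_spec()] objects in session order.
#' @param n_blocks,n_train_per_block block structure of the session.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(condition, trials, n_blocks, n_train_per_block) {
  structure(list(condition = condition, trials = trials,
                 n_blocks = as.integer(n_blocks),
                 n_train_per_block = as.integer(n_train_per_block)),
            class = "experiment_design")
}

#' Number of trials in a design
#' @param design an `experiment_design`.
#' @export
n_trials <- function(design) length(design$trials)

#' Build a cued multi-modal learning design
#'
#' Constructs `n_blocks` blocks of `n_train_per_block` training trials
#' followed by one test trial.  Within a block each diagonal object
#' configuration (and its paired sound) appears `n_train_per_block / 2`
#' times in seeded pseudo-random order (a Fisher-Yates shuffle, re-drawn
#' whenever more than two identical configurations would run
#' consecutively).  Test-trial sounds alternate across blocks so each sound
#' is tested equally often (up to rounding).  On training trials in the
#' `face` and `square` conditions the lower box of the current
#' configuration is cued; in `no_cue` every cue vector is zero.  Test
#' trials never carry objects or cues.
#'
#' @param condition `"face"`, `"square"` or `"no_cue"`.
#' @param n_blocks number of blocks (>= 1).
#' @param n_train_per_block training trials per block (must be even).
#' @param seed integer seed; identical seeds give identical designs.
#' @return An `experiment_design` with `n_blocks * (n_train_per_block + 1)`
#'   trials.
#' @examples
#' d <- build_design("face", 4, 6, seed = 1)
#' n_trials(d)  # 28
#' @export
build_design <- function(condition = c("face", "square", "no_cue"),
                         n_blocks = 4L, n_train_per_block = 6L, seed = 1L) {
  condition <- match.arg(condition)
  if (n_train_per_block %% 2 != 0)
    stop("invalid design: n_train_per_block must be even so the two ",
         "configurations balance within a block")
  if (n_blocks < 1) stop("invalid design: n_blocks must be >= 1")
  set.seed(seed)
  trials <- vector("list", n_blocks * (n_train_per_block + 1))
  idx <- 0L
  for (b in seq_len(n_blocks)) {
    configs <- shuffle_configs(n_train_per_block)
    for (j in seq_len(n_train_per_block)) {
      cfg <- configs[j]
      objects <- integer(N_AOI)
      objects[CONFIG_BOXES[[cfg]]] <- 1L
      cue <- integer(N_AOI)
      if (condition != "no_cue") cue[CONFIG_LOWER[cfg]] <- 1L
      idx <- idx + 1L
      trials[[idx]] <- trial_spec(idx, b, "training", cfg, objects, cue)
    }
    idx <- idx + 1L
    trials[[idx]] <- trial_spec(idx, b, "test", ((b - 1L) %% 2L) + 1L,
                                integer(N_AOI), integer(N_AOI))
  }
  experiment_design(condition, trials, n_blocks, n_train_per_block)
}

# Seeded shuffle of config labels with a mild anti-streak constraint:
# reject orders that place more than two identical configurations in a row.
shuffle_configs <- function(n_train) {
  labels <- rep(1:2, each = n_train / 2)
  repeat {
    out <- sample(labels)
    if (max(rle(out)$lengths) <= 2 || n_train < 2) return(out)
  }
}

#' Check an experiment design against its structural invariants
#'
#' Reports, never raises: returns a character vector of violation
#' descriptions (empty if the design is valid), each naming the offending
#' trial and the rule broken.
#'
#' @param design an `experiment_design`.
#' @return Character vector of violations; `character(0)` for a valid design.
#' @export
validate_design <- function(design) {
  v <- character(0)
  trials <- design$trials
  diag_pairs <- lapply(CONFIG_BOXES, sort)
  for (tr in trials) {
    who <- sprintf("trial %d", tr$index)
    if (tr$objects[N_AOI] != 0 || tr$cue[N_AOI] != 0)
      v <- c(v, paste0(who, ": AOI 'OTHER' must never carry an object or cue"))
    if (tr$kind == "test") {
      if (any(tr$objects != 0))
        v <- c(v, paste0(who, ": test trials must have all-zero objects"))
      if (any(tr$cue != 0))
        v <- c(v, paste0(who, ": cues are only allowed on training trials"))
    } else {
      on <- sort(which(tr$objects[1:4] == 1))
      if (sum(tr$objects) != 2 || !any(vapply(diag_pairs, identical, TRUE, on)))
        v <- c(v, paste0(who, ": training trials must place exactly two ",
                         "objects on a diagonal box pair"))
      if (sum(tr$cue) > 1)
        v <- c(v, paste0(who, ": at most one box may be cued"))
      ci <- which(tr$cue == 1)
      if (length(ci) == 1 && (!(ci %in% c(3L, 4L)) || tr$objects[ci] != 1))
        v <- c(v, paste0(who, ": a cue must coincide with an object in a ",
                         "lower box (BL or BR)"))
      if (design$condition == "no_cue" && any(tr$cue != 0))
        v <- c(v, paste0(who, ": condition no_cue requires all-zero cues"))
    }
  }
  # Block structure: n_train_per_block training trials then one test trial.
  kinds <- vapply(trials, `[[`, "", "kind")
  blocks <- vapply(trials, `[[`, 0L, "block")
  per_block <- design$n_train_per_block + 1L
  if (length(trials) != design$n_blocks * per_block) {
    v <- c(v, sprintf("trial count %d does not match %d blocks of %d",
                      length(trials), design$n_blocks, per_block))
  } else {
    for (b in seq_len(design$n_blocks)) {
      span <- ((b - 1L) * per_block + 1L):(b * per_block)
      if (any(blocks[span] != b) ||
          any(kinds[span] != c(rep("training", design$n_train_per_block), "test")))
        v <- c(v, sprintf("block %d: expected %d training trials followed by one test trial",
                          b, design$n_train_per_block))
      cfgs <- vapply(trials[span[kinds[span] == "training"]], `[[`, 0L, "sound_id")
      if (length(cfgs) == design$n_train_per_block &&
          sum(cfgs == 1L) != sum(cfgs == 2L))
        v <- c(v, sprintf("block %d: the two configurations must appear equally often", b))
    }
    test_sounds <- vapply(trials[kinds == "test"], `[[`, 0L, "sound_id")
    if (abs(sum(test_sounds == 1L) - sum(test_sounds == 2L)) > 1)
      v <- c(v, "test-trial sounds must balance across blocks (within one)")
  }
  v
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> condition=%s, %d blocks x (%d training + 1 test) = %d trials\n",
              x$condition, x$n_blocks, x$n_train_per_block, n_trials(x)))
  invisible(x)
}

# Per-trial design matrices used by the likelihood: sound ids, object and
# cue indicators (T x 5 each).
design_matrices <- function(design) {
  tt <- design$trials
  list(sound = vapply(tt, `[[`, 0L, "sound_id"),
       objects = do.call(rbind, lapply(tt, `[[`, "objects")),
       cue = do.call(rbind, lapply(tt, `[[`, "cue")))
}

#' Write a design to JSON
#' @param design an `experiment_design`.
#' @param path output file.
#' @export
write_design_json <- function(design, path) {
  obj <- list(condition = design$condition,
              n_blocks = design$n_blocks,
              n_train_per_block = design$n_train_per_block,
              trials = lapply(design$trials, function(tr)
                list(index = tr$index, block = tr$block, kind = tr$kind,
                     sound_id = tr$sound_id, objects = tr$objects, cue = tr$cue)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a design from JSON
#' @param path file written by [write_design_json()].
#' @return An `experiment_design`.
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trials <- lapply(obj$trials, function(tr)
    trial_spec(tr$index, tr$block, tr$kind, tr$sound_id,
               unlist(tr$objects), unlist(tr$cue)))
  experiment_design(obj$condition, trials, obj$n_blocks, obj$n_train_per_block)
}
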