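# Posterior summaries: sample-wise misclassification against a known
# partition, consensus clustering of the co-assignment matrix, occupancy
# shares and per-cluster parameter intervals.  All summaries are
# partition-based, so mixture label switching never needs resolving.

# Optimal label matching between two partitions' label sets: maximize the
# total confusion-matrix overlap over injective maps (branch-and-bound
# enumeration; label counts here are small).  Returns the score and the
# row -> column map (NA for unmatched or zero-overlap rows).
best_assignment <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) > ncol(C)) {
    r <- best_assignment(t(C))
    map <- rep(NA_integer_, nrow(C))
    ok <- !is.na(r$map)
    map[r$map[ok]] <- which(ok)
    return(list(score = r$score, map = map))
  }
  K <- nrow(C)
  G <- ncol(C)
  best_score <- -1
  best_map <- rep(NA_integer_, K)
  used <- logical(G)
  map <- integer(K)
  row_max <- apply(C, 1, max)
  rec <- function(r, acc) {
    if (r > K) {
      if (acc > best_score) {
        best_score <<- acc
        best_map <<- map
      }
      return()
    }
    if (acc + sum(row_max[r:K]) <= best_score) return()
    for (g in seq_len(G)) {
      if (!used[g]) {
        used[g] <<- TRUE
        map[r] <<- g
        rec(r + 1L, acc + C[r, g])
        used[g] <<- FALSE
      }
    }
  }
  rec(1L, 0)
  best_map[best_map >= 1 & C[cbind(seq_len(K), best_map)] == 0] <- NA_integer_
  list(score = best_score, map = best_map)
}

chain_z <- function(chain) {
  if (inherits(chain, "posterior_chain")) chain$z else as.matrix(chain)
}

# Unique assignment patterns and their sample counts (most sweeps repeat
# the same partition, so summaries are computed once per pattern).
unique_patterns <- function(z) {
  keys <- apply(z, 1, paste, collapse = ",")
  first <- which(!duplicated(keys))
  list(rows = first, weight = as.vector(table(keys)[unique(keys)]),
       key_of = match(keys, keys[first]))
}

#' Posterior misclassification against a known partition
#'
#' For each posterior sample, matches the sampled tables to the true
#' groups by the label assignment minimizing mismatches (optimal matching
#' over the confusion matrix) and counts the fraction of infants at a
#' wrong table; the fractions are averaged over samples.  Invariant to
#' relabeling tables or true groups.
#'
#' @param chain a `posterior_chain` (or a samples-by-infants assignment
#'   matrix).
#' @param truth integer vector of true group labels, one per infant.
#' @return Mean misclassified fraction in `[0, 1]`.
#' @export
misclassification <- function(chain, truth) {
  z <- chain_z(chain)
  n <- ncol(z)
  if (length(truth) != n)
    stop("truth has length ", length(truth), " but the chain covers ",
         n, " infants")
  up <- unique_patterns(z)
  truth <- as.integer(factor(truth))
  mis <- vapply(up$rows, function(r) {
    C <- table(factor(z[r, ]), factor(truth))
    (n - best_assignment(C)$score) / n
  }, 0)
  sum(mis * up$weight) / nrow(z)
}

#' Most frequent number of occupied tables
#'
#' @param chain a `posterior_chain`.
#' @return The modal table count across samples; ties break toward the
#'   smaller count.
#' @export
modal_table_count <- function(chain) {
  counts <- if (inherits(chain, "posterior_chain") && !is.null(chain$n_tables))
    chain$n_tables
  else apply(chain_z(chain), 1, function(r) length(unique(r)))
  tt <- table(counts)
  min(as.integer(names(tt)[tt == max(tt)]))
}

#' Consensus partition and cluster summaries of a chain
#'
#' Builds the posterior co-assignment matrix (fraction of samples in which
#' two infants share a table), cuts its average-linkage clustering at
#' `1 - cut` to obtain the consensus partition, then matches each sample's
#' tables to the consensus clusters (optimal overlap matching) to
#' accumulate occupancy shares and pooled per-cluster parameter samples.
#'
#' @param chain a `posterior_chain`.
#' @param cut co-assignment threshold for the consensus cut (default .5,
#'   majority rule).
#' @return A `cluster_summary`: `consensus_partition` (label per infant),
#'   `occupancy` (shares summing to 1), `param_median` and 68%/95%
#'   interval matrices (cluster x parameter), and `param_samples` (one
#'   samples-by-parameters matrix per cluster, `NA` rows where a sample
#'   had no matching table).
#' @export
consensus_partition <- function(chain, cut = 0.5) {
  stopifnot(inherits(chain, "posterior_chain"))
  z <- chain$z
  S <- nrow(z)
  n <- ncol(z)
  if (S == 0) stop("chain has no post-burn-in samples")
  up <- unique_patterns(z)
  P <- matrix(0, n, n)
  for (j in seq_along(up$rows)) {
    r <- z[up$rows[j], ]
    P <- P + up$weight[j] * outer(r, r, "==")
  }
  P <- P / S
  consensus <- if (n == 1) 1L else
    unname(cutree(hclust(as.dist(1 - P), method = "average"), h = 1 - cut))
  K <- max(consensus)
  pn <- chain$param_names
  Pdim <- length(pn)
  occ_counts <- numeric(K)
  samples <- lapply(seq_len(K), function(k)
    matrix(NA_real_, S, Pdim, dimnames = list(NULL, pn)))
  # Matching is computed once per unique pattern and reused for its samples.
  for (j in seq_along(up$rows)) {
    r0 <- up$rows[j]
    zs <- z[r0, ]
    C <- table(factor(zs, levels = seq_len(max(zs))),
               factor(consensus, levels = seq_len(K)))
    map <- best_assignment(C)$map   # sampled table -> consensus cluster
    occ <- numeric(K)
    for (tbl in seq_along(map)) {
      if (!is.na(map[tbl])) occ[map[tbl]] <- occ[map[tbl]] + sum(zs == tbl)
    }
    occ_counts <- occ_counts + occ * up$weight[j]
    rows_j <- which(up$key_of == j)
    for (tbl in seq_along(map)) {
      if (is.na(map[tbl])) next
      for (r in rows_j)
        samples[[map[tbl]]][r, ] <- chain$tables[[r]][tbl, ]
    }
  }
  occupancy <- occ_counts / sum(occ_counts)
  qs <- function(m, p) apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) NA_real_ else quantile(col, p, names = FALSE)
  })
  summarize <- function(p) t(vapply(samples, qs, numeric(Pdim), p = p))
  out <- list(consensus_partition = consensus, occupancy = occupancy,
              param_median = summarize(0.5),
              ci68_low = summarize(0.16), ci68_high = summarize(0.84),
              ci95_low = summarize(0.025), ci95_high = summarize(0.975),
              param_samples = samples, n_samples = S,
              co_assignment = P, param_names = pn)
  colnames(out$param_median) <- pn
  structure(out, class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  K <- length(x$occupancy)
  cat(sprintf("<cluster_summary> %d consensus cluster%s\n", K,
              if (K == 1) "" else "s"))
  for (k in seq_len(K)) {
    cat(sprintf("  cluster %d (occupancy %.1f%%): ", k, 100 * x$occupancy[k]))
    show <- intersect(c("beta_object", "beta_cue", "a1", "a2"), x$param_names)
    cat(paste(sprintf("%s=%.3f", show, x$param_median[k, show]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pooled posterior samples of one parameter for one consensus cluster
#'
#' @param summary a [consensus_partition()] result.
#' @param param parameter name (e.g. `"beta_cue"`, `"a1"`).
#' @param cluster cluster index; defaults to the largest-occupancy cluster.
#' @return Numeric vector of matched posterior draws.
#' @export
cluster_param_samples <- function(summary, param,
                                  cluster = which.max(summary$occupancy)) {
  s <- summary$param_samples[[cluster]][, param]
  s[!is.na(s)]
}

#' Plot cue-use against learning rate per consensus cluster
#'
#' Circles are centered at the cluster medians of the cue coefficient and
#' the first-order association coefficient, sized by occupancy, with 68%
#' credible-interval whiskers.
#'
#' @param x a `cluster_summary`.
#' @param ... passed to [plot()].
#' @export
plot.cluster_summary <- function(x, ...) {
  cx <- x$param_median[, "beta_cue"]
  cy <- x$param_median[, "a1"]
  xl <- range(x$ci68_low[, "beta_cue"], x$ci68_high[, "beta_cue"])
  yl <- range(x$ci68_low[, "a1"], x$ci68_high[, "a1"])
  plot(cx, cy, xlim = xl, ylim = yl, cex = 1 + 6 * sqrt(x$occupancy),
       pch = 21, bg = "grey80", xlab = "cue coefficient",
       ylab = "association coefficient (linear)", ...)
  segments(x$ci68_low[, "beta_cue"], cy, x$ci68_high[, "beta_cue"], cy,
           lty = 2)
  segments(cx, x$ci68_low[, "a1"], cx, x$ci68_high[, "a1"], lty = 2)
  invisible(x)
}
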