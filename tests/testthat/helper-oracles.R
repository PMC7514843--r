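# Independent oracles and small generators shared across the suite.

# Brute-force maximization of Shannon entropy over {l <= p <= u, sum p = 1}
# by multi-scale grid search on the free coordinates (p_k is implied).
# Entirely independent of the package's water-filling solver. The objective
# is concave on a convex region, so refining the grid around the incumbent
# converges to the global maximum.
grid_max_entropy <- function(l, u, steps = 17L, max_iter = 60L) {
  k <- length(l)
  if (k == 1L) return(list(p = 1, entropy = 0))
  ent <- function(P) {
    P[P < 0] <- 0  # grid residuals can undershoot zero by ~1e-12
    Q <- P * log2(P)
    Q[!is.finite(Q)] <- 0
    -rowSums(Q)
  }
  # a feasible incumbent: interpolate between the bound vectors so sum = 1
  t0 <- (1 - sum(l)) / max(sum(u) - sum(l), .Machine$double.eps)
  best_p <- l + t0 * (u - l)
  best_H <- ent(matrix(best_p, 1L))
  lo <- l[-k]; hi <- u[-k]  # search window on the free coordinates
  for (it in seq_len(max_iter)) {
    grids <- Map(function(a, b) seq(a, b, length.out = steps), lo, hi)
    G <- as.matrix(expand.grid(grids))
    pk <- 1 - rowSums(G)
    ok <- pk >= l[k] - 1e-12 & pk <= u[k] + 1e-12
    improved <- FALSE
    if (any(ok)) {
      P <- cbind(G[ok, , drop = FALSE], pk[ok])
      H <- ent(P)
      i <- which.max(H)
      if (H[i] > best_H + 1e-15) {
        best_H <- H[i]; best_p <- unname(P[i, ]); improved <- TRUE
      }
    }
    cell <- (hi - lo) / (steps - 1)
    free <- best_p[-k]
    w <- if (improved) (hi - lo) / 2 else cell  # shrink only on failure
    lo <- pmax(l[-k], free - w)
    hi <- pmin(u[-k], free + w)
    if (!improved && max(cell) < 1e-10) break
  }
  # polish: ascent along pairwise exchange directions e_i - e_j (the feasible
  # directions of the box-and-simplex region); each 1-D problem is concave
  h1 <- function(p) sum(ifelse(p > 0, -p * log2(p), 0))
  p <- best_p
  for (sweep in 1:30) {
    moved <- FALSE
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      dlo <- max(l[i] - p[i], p[j] - u[j])
      dhi <- min(u[i] - p[i], p[j] - l[j])
      if (dhi - dlo < 1e-14) next
      f <- function(d) {
        q <- p; q[i] <- q[i] + d; q[j] <- q[j] - d
        h1(q)
      }
      opt <- stats::optimize(f, c(dlo, dhi), maximum = TRUE, tol = 1e-12)
      d <- opt$maximum
      if (opt$objective > h1(p) + 1e-14) {
        p[i] <- p[i] + d; p[j] <- p[j] - d
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  if (h1(p) > best_H) { best_p <- p; best_H <- h1(p) }
  list(p = best_p, entropy = as.numeric(best_H))
}

# Random feasible probability-interval systems: boxes around a random simplex
# point (always non-empty), plus IDM/NPI boxes from random integer counts.
random_interval_system <- function(k) {
  kind <- sample(c("box", "idm", "npi"), 1)
  if (kind == "box") {
    p0 <- stats::rgamma(k, 1) + 1e-3
    p0 <- p0 / sum(p0)
    wl <- stats::runif(k, 0.02, 0.4)
    wu <- stats::runif(k, 0.02, 0.4)
    list(l = pmax(0, p0 - wl), u = pmin(1, p0 + wu))
  } else {
    counts <- stats::rpois(k, sample(1:12, 1))
    if (sum(counts) == 0) counts[sample.int(k, 1)] <- 1L
    N <- sum(counts)
    if (kind == "idm") {
      s <- sample(c(1, 2), 1)
      list(l = counts / (N + s), u = (counts + s) / (N + s))
    } else {
      list(l = pmax(0, (counts - 1) / N), u = pmin((counts + 1) / N, 1))
    }
  }
}

# Small random weighted dataset over one predictor with t values; no missing
# values. Used for the limit-recovery and containment properties.
random_weighted_dataset <- function(n = 30L, t = 3L) {
  sch <- accident_schema(list(
    variable_spec("X", seq_len(t), missing_allowed = TRUE),
    variable_spec("SEV", 1:2, c("slight", "fatal"))))
  accident_dataset(
    data.frame(X = sample.int(t, n, replace = TRUE),
               SEV = sample(1:2, n, replace = TRUE, prob = c(.7, .3))),
    schema = sch, weights = stats::runif(n, 0.5, 2))
}

# Plain info-gain (precise), computed from the package's entropy primitives;
# the reference for the s -> 0 limit of the imprecise gain.
precise_info_gain <- function(ds, variable) {
  tab <- table(factor(ds$data$SEV, levels = ds$schema$SEV$values))
  w <- ds$weights
  cls <- ds$schema$SEV$values
  marg <- vapply(cls, function(c) sum(w[ds$data$SEV == c]), numeric(1))
  shannon_entropy(marg / sum(marg)) - conditional_entropy(ds, variable)
}

# Depth of a nested-list tree (number of split nodes on the longest path)
# and the summed leaf weights, by direct traversal.
tree_depth <- function(node) {
  if (is.null(node$var)) return(0L)
  1L + max(vapply(node$branches, tree_depth, integer(1)))
}
leaf_weight_sum <- function(node) {
  if (is.null(node$var)) return(node$weight)
  sum(vapply(node$branches, leaf_weight_sum, numeric(1)))
}
leaf_weights <- function(node) {
  if (is.null(node$var)) return(node$weight)
  unlist(lapply(node$branches, leaf_weights))
}

# Cached mid-size pipeline run with a planted rule, shared by several tests.
.shared <- new.env()
shared_planted_run <- function() {
  if (is.null(.shared$run)) {
    pr <- planted_rule(c(SE = 1L, F_T = 2L, S_W = 4L, ACT_TY = 3L),
                       fatal_probability = 0.6, target_prevalence = 0.02,
                       partition = "intersection")
    sc <- synthetic_config(n_records = 8000, planted = list(pr), seed = 2026)
    .shared$run <- run_pipeline(pipeline_config(synthetic = sc))
  }
  .shared$run
}
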