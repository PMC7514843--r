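# Split criteria: Shannon entropy / info-gain ratio, and the two imprecise
# criteria built on credal sets of per-class probability intervals (IDM and
# the approximate NPI model), scored through the maximum entropy over the set.

.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a class distribution, in bits
#'
#' @param p Numeric vector of class probabilities (non-negative, summing to 1
#'   within 1e-9). The `0 * log2(1/0)` term is taken as 0.
#' @return Entropy in bits, between 0 and `log2(length(p))`.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5))   # 1
#' shannon_entropy(c(0.25, 0.75)) # 0.8112781
shannon_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a probability distribution (non-negative, summing to 1)")
  .entropy_bits(p)
}

#' Per-class probability intervals
#'
#' A box of per-class `[lower, upper]` bounds whose intersection with the
#' probability simplex is a (non-empty) credal set.
#'
#' @param lower,upper Numeric vectors in `[0, 1]`, `lower <= upper`
#'   componentwise, with `sum(lower) <= 1 <= sum(upper)`.
#' @return A `probability_intervals` object.
#' @export
probability_intervals <- function(lower, upper) {
  stopifnot(length(lower) == length(upper))
  if (any(lower < -1e-12) || any(upper > 1 + 1e-12) || any(lower > upper + 1e-12))
    stop("need 0 <= lower <= upper <= 1 componentwise")
  if (sum(lower) > 1 + 1e-9 || sum(upper) < 1 - 1e-9)
    stop("credal set is empty: need sum(lower) <= 1 <= sum(upper)")
  structure(list(lower = pmin(pmax(lower, 0), 1),
                 upper = pmin(pmax(upper, 0), 1)),
            class = "probability_intervals")
}

#' @export
print.probability_intervals <- function(x, ...) {
  cat("probability_intervals:\n")
  for (i in seq_along(x$lower))
    cat(sprintf("  class %d: [%.6f, %.6f]\n", i, x$lower[i], x$upper[i]))
  invisible(x)
}

#' Imprecise-Dirichlet-model probability intervals
#'
#' For class counts `n_i` out of `N` total, the IDM gives the interval
#' `[n_i / (N + s), (n_i + s) / (N + s)]` for each class. Counts may be
#' real-valued (fractional instance weights). The hyperparameter `s` controls
#' the interval width `s / (N + s)`; `s = 1` is the conventional choice.
#'
#' @param counts Non-negative (possibly fractional) per-class counts.
#' @param s IDM hyperparameter, `s > 0`.
#' @return A `probability_intervals` object.
#' @export
#' @examples
#' idm_intervals(c(3, 6), s = 1)  # [0.3, 0.4], [0.6, 0.7]
idm_intervals <- function(counts, s = 1) {
  if (s <= 0) stop("s must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  if (N <= 0) stop("total count is zero; intervals undefined")
  probability_intervals(counts / (N + s), (counts + s) / (N + s))
}

#' Approximate-NPI probability intervals
#'
#' The parameter-free nonparametric predictive inference box
#' `[max(0, (n_i - 1) / N), min((n_i + 1) / N, 1)]` per class.
#'
#' @param counts Non-negative (possibly fractional) per-class counts.
#' @return A `probability_intervals` object.
#' @export
#' @examples
#' anpim_intervals(c(3, 6))  # [2/9, 4/9], [5/9, 7/9]
anpim_intervals <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  if (N <= 0) stop("total count is zero; intervals undefined")
  probability_intervals(pmax(0, (counts - 1) / N), pmin((counts + 1) / N, 1))
}

# Water-filling maximizer of Shannon entropy over {l <= p <= u, sum(p) = 1}.
# The objective is strictly concave and symmetric; the KKT solution clamps
# every coordinate to a common level lambda: p_i = min(max(lambda, l_i), u_i),
# with lambda fixed by the simplex constraint (sum is nondecreasing in lambda,
# solved by bisection). Residual after bisection is spread over the unclamped
# coordinates so the simplex constraint holds to machine precision.
.wf_max_entropy <- function(l, u, tol = 1e-12) {
  lo <- min(l); hi <- max(u)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    s <- sum(pmin(pmax(mid, l), u))
    if (s < 1) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  lam <- (lo + hi) / 2
  p <- pmin(pmax(lam, l), u)
  free <- p > l + 1e-15 & p < u - 1e-15
  resid <- 1 - sum(p)
  if (any(free)) p[free] <- p[free] + resid / sum(free)
  p <- pmin(pmax(p, l), u)
  list(p = p, entropy = .entropy_bits(p))
}

#' Maximum-entropy distribution over an interval credal set
#'
#' Finds the distribution of maximum Shannon entropy in the credal set defined
#' by per-class probability intervals intersected with the simplex, and its
#' entropy H*. Solved by water-filling: the optimum clamps every coordinate to
#' a common level within its interval, with the level fixed by bisection so
#' the probabilities sum to one.
#'
#' @param intervals A [probability_intervals()] object.
#' @return A list with `p` (the maximizing distribution) and `entropy` (H*,
#'   bits).
#' @export
#' @examples
#' max_entropy_distribution(probability_intervals(c(0.3, 0.6), c(0.4, 0.7)))
max_entropy_distribution <- function(intervals) {
  stopifnot(inherits(intervals, "probability_intervals"))
  .wf_max_entropy(intervals$lower, intervals$upper)
}

# H* directly from weighted class counts under a credal model.
.hstar_counts <- function(counts, model, s = 1) {
  N <- sum(counts)
  if (N <= 0) return(NA_real_)
  if (model == "IDM") {
    l <- counts / (N + s); u <- (counts + s) / (N + s)
  } else {
    l <- pmax(0, (counts - 1) / N); u <- pmin((counts + 1) / N, 1)
  }
  .wf_max_entropy(l, u)$entropy
}

# --- dataset-level scoring -------------------------------------------------

# Vectorized binary entropy from class-1 count a and total t (bits).
.h2 <- function(a, t) {
  p <- ifelse(t > 0, a / t, 0)
  q <- 1 - p
  out <- numeric(length(p))
  nz <- p > 0 & p < 1
  out[nz] <- -(p[nz] * log2(p[nz]) + q[nz] * log2(q[nz]))
  out
}

# Vectorized H* for binary classes. For k = 2 the water-filling solution is
# closed-form: p1 is clamped to 1/2 within its feasible range
# [max(l1, 1 - u2), min(u1, 1 - l2)].
.hstar2 <- function(a, b, model, s = 1) {
  t <- a + b
  if (model == "IDM") {
    l1 <- a / (t + s); u1 <- (a + s) / (t + s)
    l2 <- b / (t + s); u2 <- (b + s) / (t + s)
  } else {
    l1 <- pmax(0, (a - 1) / t); u1 <- pmin((a + 1) / t, 1)
    l2 <- pmax(0, (b - 1) / t); u2 <- pmin((b + 1) / t, 1)
  }
  lo <- pmax(l1, 1 - u2); hi <- pmin(u1, 1 - l2)
  p1 <- pmin(pmax(0.5, lo), hi)
  .h2(p1 * t, t)
}

# Fast binary-class criterion evaluation for tree induction. w1/w2 are the
# per-record weights masked by class; returns the score (NA when undefined)
# and whether the split is admissible (>= 2 branches with observed weight
# >= min_leaf_weight).
.split_eval2 <- function(x, w1, w2, criterion, s, min_leaf_weight) {
  obs <- !is.na(x)
  if (!any(obs)) return(list(score = NA_real_, ok = FALSE, nvals = 0L))
  tab <- rowsum(cbind(w1[obs], w2[obs]), group = x[obs], reorder = TRUE)
  a <- tab[, 1]; b <- tab[, 2]
  bt <- a + b
  Wo <- sum(bt)
  if (Wo <= 0) return(list(score = NA_real_, ok = FALSE, nvals = 0L))
  W <- sum(w1) + sum(w2)
  frac <- Wo / W
  pb <- bt / Wo
  ok <- sum(bt >= min_leaf_weight) >= 2L
  A <- sum(a); B <- sum(b)
  if (criterion == "IGR") {
    hx <- .entropy_bits(pb)
    if (hx <= 0) return(list(score = NA_real_, ok = FALSE, nvals = nrow(tab)))
    gain <- .h2(A, A + B) - sum(pb * .h2(a, bt))
    return(list(score = frac * gain / hx, ok = ok, nvals = nrow(tab)))
  }
  model <- if (criterion == "IIG") "IDM" else "NPI"
  sc <- frac * (.hstar2(A, B, model, s) - sum(pb * .hstar2(a, b, model, s)))
  list(score = sc, ok = ok, nvals = nrow(tab))
}

# Weighted class-by-value cross-tabulation for one candidate variable.
# Returns NULL when the variable has no observed weight.
.cross_tab <- function(x, y, w, class_levels) {
  obs <- !is.na(x)
  if (!any(obs) || sum(w[obs]) <= 0) return(NULL)
  xo <- x[obs]; yo <- y[obs]; wo <- w[obs]
  ymat <- outer(yo, class_levels, `==`) * wo
  tab <- rowsum(ymat, group = xo, reorder = TRUE)
  W <- sum(w)
  list(tab = tab, branch_w = rowSums(tab), obs_w = sum(wo), total_w = W,
       values = as.integer(rownames(tab)))
}

# Criterion value for one variable on weighted records. Missing values of x
# are handled the C4.5 way: the criterion is computed on the observed-weight
# records and multiplied by the observed-weight fraction. Returns NA when the
# score is undefined (variable entirely missing, or constant for IGR).
# Dispatches to the closed-form binary path when the class is binary.
.crit_value <- function(x, y, w, criterion, s, class_levels) {
  if (length(class_levels) == 2L) {
    return(.split_eval2(x, w * (y == class_levels[1]),
                        w * (y == class_levels[2]), criterion, s, Inf)$score)
  }
  ct <- .cross_tab(x, y, w, class_levels)
  if (is.null(ct)) return(NA_real_)
  frac <- ct$obs_w / ct$total_w
  pb <- ct$branch_w / ct$obs_w
  marg <- colSums(ct$tab)
  if (criterion == "IGR") {
    hx <- .entropy_bits(pb)
    if (hx <= 0) return(NA_real_)
    hc <- .entropy_bits(marg / ct$obs_w)
    hcond <- sum(pb * apply(ct$tab, 1L, function(r) {
      tw <- sum(r); if (tw <= 0) 0 else .entropy_bits(r / tw)
    }))
    return(frac * (hc - hcond) / hx)
  }
  model <- if (criterion == "IIG") "IDM" else "NPI"
  hstar_marg <- .hstar_counts(marg, model, s)
  hstar_cond <- sum(pb * apply(ct$tab, 1L, .hstar_counts, model = model, s = s))
  frac * (hstar_marg - hstar_cond)
}

.get_xyw <- function(ds, variable) {
  stopifnot(inherits(ds, "accident_dataset"))
  if (!variable %in% names(ds$data)) stop("unknown variable '", variable, "'")
  list(x = ds$data[[variable]], y = ds$data$SEV, w = ds$weights,
       levels = ds$schema$SEV$values)
}

#' Conditional entropy of the severity class given a variable, in bits
#'
#' `H(C | X) = sum_i p(x_i) H_{D_i}(C)`, with all probabilities estimated as
#' relative frequencies of observed weight; records missing `X` are left out.
#'
#' @param ds An `accident_dataset`.
#' @param variable Name of a predictor variable.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(ds, variable) {
  v <- .get_xyw(ds, variable)
  ct <- .cross_tab(v$x, v$y, v$w, v$levels)
  if (is.null(ct)) stop("'", variable, "' is entirely missing; H(C|X) undefined")
  pb <- ct$branch_w / ct$obs_w
  sum(pb * apply(ct$tab, 1L, function(r) {
    tw <- sum(r); if (tw <= 0) 0 else .entropy_bits(r / tw)
  }))
}

.criterion_score <- function(criterion, variable, value, s = NA_real_) {
  structure(list(criterion = criterion, variable = variable,
                 value = value, s = s, defined = !is.na(value)),
            class = "criterion_score")
}

#' @export
print.criterion_score <- function(x, ...) {
  cat(sprintf("%s(%s) = %s%s\n", x$criterion, x$variable,
              if (x$defined) format(x$value) else "undefined",
              if (!is.na(x$s)) sprintf(" [s=%g]", x$s) else ""))
  invisible(x)
}

#' Information-gain ratio of a variable
#'
#' `IGR = (H(C) - H(C|X)) / H(X)`, the C4.5 split criterion. Undefined
#' (`defined = FALSE`) when `X` is constant or entirely missing. Under
#' missing values the gain is computed on the observed-weight records and
#' scaled by the observed-weight fraction.
#'
#' @param ds An `accident_dataset`.
#' @param variable Name of a predictor variable.
#' @return A `criterion_score`.
#' @export
info_gain_ratio <- function(ds, variable) {
  v <- .get_xyw(ds, variable)
  .criterion_score("IGR", variable,
                   .crit_value(v$x, v$y, v$w, "IGR", NA, v$levels))
}

#' Imprecise information gain of a variable over a credal model
#'
#' `H*(K(C)) - sum_i p(x_i) H*(K(C | X = x_i))`, where `K` is the credal set
#' of the chosen model built from the (possibly fractional) class counts of
#' each branch and H* is the maximum entropy over the set. Unlike the precise
#' info-gain the result can be negative, which marks a variable that worsens
#' the information on the class.
#'
#' @param ds An `accident_dataset`.
#' @param variable Name of a predictor variable.
#' @param model `"IDM"` (imprecise Dirichlet, uses `s`) or `"NPI"`
#'   (approximate nonparametric predictive inference, parameter-free).
#' @param s IDM hyperparameter (default 1).
#' @return A `criterion_score` with criterion `"IIG"` or `"ANPIM"`.
#' @export
imprecise_gain <- function(ds, variable, model = c("IDM", "NPI"), s = 1) {
  model <- match.arg(model)
  v <- .get_xyw(ds, variable)
  crit <- if (model == "IDM") "IIG" else "ANPIM"
  .criterion_score(crit, variable,
                   .crit_value(v$x, v$y, v$w, crit, s, v$levels),
                   s = if (model == "IDM") s else NA_real_)
}
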