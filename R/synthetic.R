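# Synthetic generator for DGT-style categorical accident records: the coded
# schema value sets with skewed marginals, configurable class imbalance and
# missingness, and planted antecedent-to-fatal rules with known conditional
# probabilities so the whole pipeline is testable without the original
# microdata.

# Default per-variable marginals. Uniform would be unrealistic for several
# variables whose published frequency tables are strongly skewed (dry/clean
# road surface, good weather, male drivers, "other maneuver", appropriate
# speed, no vehicle anomaly); those skews are encoded here as editable
# defaults, not fitted values.
.default_marginals <- function(schema) {
  skew <- list(
    SE       = c(.24, .25, .24, .27),
    F_T      = c(.08, .25, .38, .29),
    S_W      = c(.14, .16, .45, .25),
    I_L      = c(.17, .83),
    TR_N_INT = c(.92, .08),
    I_T      = c(.23, .60, .15, .02),
    PR       = c(.002, .28, .24, .30, .10, .05, .028),
    RO_SU    = c(.905, .002, .084, .002, .007),
    LUM      = c(.656, .043, .299, .002),
    WE_CO    = c(.927, .002, .061, .010),
    RES_VIS  = c(.911, .004, .008, .008, .006, .005, .058),
    PAV      = c(.974, .026),
    ACT_TY   = c(.837, .066, .017, .050, .030),
    AG_FR    = c(.245, .356, .380, .019),
    SEX      = c(.738, .262),
    MAN      = c(.262, .018, .084, .025, .077, .003, .013, .518),
    SP_IN    = c(.044, .001, .955),
    DR_INFR  = c(.523, .124, .006, .006, .017, .324),
    OL_VEH   = c(.166, .834),
    VEH_TY   = c(.364, .618, .014, .004),
    AN       = c(.990, .010),
    O_L      = c(.687, .145, .168)
  )
  out <- list()
  for (v in names(schema)) {
    if (v == "SEV") next
    p <- skew[[v]]
    if (is.null(p) || length(p) != length(schema[[v]]$values))
      p <- rep(1, length(schema[[v]]$values))
    out[[v]] <- p / sum(p)
  }
  out
}

# Default per-variable missingness fractions, echoing the pattern of the
# published counts (visibility restrictions and priority regulation largely
# unrecorded; core variables nearly complete). Variables whose schema forbids
# missing values get 0.
.default_missingness <- function(schema) {
  f <- c(TR_N_INT = .18, PR = .60, RO_SU = .05, WE_CO = .06, RES_VIS = .72,
         PAV = .015, SEX = .001, MAN = .045, SP_IN = .28, DR_INFR = .12,
         OL_VEH = .42, VEH_TY = .002, AN = .20)
  out <- stats::setNames(numeric(length(schema) - 1L),
                         setdiff(names(schema), "SEV"))
  for (v in names(out))
    if (schema[[v]]$missing_allowed && v %in% names(f)) out[v] <- f[[v]]
  out
}

#' A planted antecedent-to-fatal rule
#'
#' Describes a ground-truth rule the generator injects: a share of records is
#' forced to match the antecedent, and those records draw their severity from
#' `Bernoulli(fatal_probability)` instead of the base rate.
#'
#' @param antecedent Named integer vector of `variable = code` conditions.
#' @param fatal_probability Probability of fatal severity among forced
#'   matches, in `(0, 1]`.
#' @param target_prevalence Fraction of all records forced to match, in
#'   `(0, 1)`.
#' @param partition Where the rule lives: `"any"`, `"intersection"` or
#'   `"non_intersection"`. Antecedent variables must apply there.
#' @return A `planted_rule` list.
#' @export
planted_rule <- function(antecedent, fatal_probability, target_prevalence,
                         partition = "any") {
  partition <- match.arg(partition, c("any", "intersection", "non_intersection"))
  stopifnot(length(antecedent) >= 1, !is.null(names(antecedent)),
            fatal_probability > 0, fatal_probability <= 1,
            target_prevalence > 0, target_prevalence < 1)
  if (anyDuplicated(names(antecedent)))
    stop("planted antecedent repeats a variable")
  structure(list(antecedent = antecedent,
                 fatal_probability = fatal_probability,
                 target_prevalence = target_prevalence,
                 partition = partition),
            class = "planted_rule")
}

#' Synthetic-data configuration
#'
#' @param n_records Number of records (default 30000, a realistic scale
#'   for several years of urban novice-driver records).
#' @param base_fatal_rate Background fatal-severity probability; must stay
#'   below 0.10, matching the strong class imbalance of the real data
#'   (default 0.07).
#' @param missingness Named per-variable missingness fractions; defaults echo
#'   the published missing-count pattern. Never applied to the class.
#' @param planted List of [planted_rule()] objects.
#' @param intersection_fraction Share of accidents at intersections
#'   (default 0.52).
#' @param marginals Optional named list of per-variable category
#'   probabilities; defaults to the built-in skewed marginals.
#' @param seed Integer random seed.
#' @param schema The schema to generate under (default [table1_schema()]).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_records = 30000L, base_fatal_rate = 0.07,
                             missingness = NULL, planted = list(),
                             intersection_fraction = 0.52, marginals = NULL,
                             seed = 1L, schema = table1_schema()) {
  stopifnot(n_records >= 1, base_fatal_rate > 0, base_fatal_rate < 0.10,
            intersection_fraction > 0, intersection_fraction < 1)
  if (inherits(planted, "planted_rule")) planted <- list(planted)
  miss <- .default_missingness(schema)
  if (!is.null(missingness)) {
    bad <- setdiff(names(missingness), names(miss))
    if (length(bad)) stop("missingness for unknown variable(s): ",
                          paste(bad, collapse = ", "))
    miss[names(missingness)] <- missingness
  }
  marg <- .default_marginals(schema)
  if (!is.null(marginals)) marg[names(marginals)] <- marginals
  # conflicting planted antecedents: same variable, different forced value
  if (length(planted) > 1L) {
    allv <- unlist(lapply(planted, function(r) r$antecedent))
    dup <- split(allv, names(allv))
    for (v in names(dup))
      if (length(unique(dup[[v]])) > 1L)
        stop("conflicting planted antecedents on variable '", v, "'")
  }
  for (r in planted) {
    part <- if (r$partition == "any") "both" else r$partition
    ok <- schema_predictors(schema, part)
    bad <- setdiff(names(r$antecedent), ok)
    if (length(bad))
      stop("planted antecedent variable(s) not applicable to partition '",
           r$partition, "': ", paste(bad, collapse = ", "))
    if (r$partition == "any") {
      strict <- schema_predictors(schema, "both")
      strict <- strict[vapply(strict, function(v)
        schema[[v]]$applies_to == "both", logical(1))]
      bad <- setdiff(names(r$antecedent), strict)
      if (length(bad))
        stop("partition-specific variable(s) in an 'any'-partition planted ",
             "rule: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(n_records = as.integer(n_records),
                 base_fatal_rate = base_fatal_rate, missingness = miss,
                 planted = planted,
                 intersection_fraction = intersection_fraction,
                 marginals = marg, seed = as.integer(seed), schema = schema),
            class = "synthetic_config")
}

#' Generate a synthetic accident dataset with a truth log
#'
#' Draws each variable independently from its categorical marginal over the
#' schema value sets (partition-specific variables only within their
#' partition), assigns severity from the base fatal rate, then forces each
#' planted rule's target share of records to match its antecedent and redraws
#' their severity from the rule's fatal probability. Missingness is applied
#' last and never to the class. The truth log records the planted
#' memberships and all realized rates.
#'
#' @param config A [synthetic_config()].
#' @return A list with `dataset` (an `accident_dataset`, partition `"both"`,
#'   including the intersection indicator column `INT`) and `truth` (the
#'   truth log).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_records
  schema <- config$schema
  INT <- stats::rbinom(n, 1L, config$intersection_fraction)
  data <- data.frame(row.names = seq_len(n))
  for (v in setdiff(names(schema), "SEV")) {
    spec <- schema[[v]]
    col <- rep(NA_integer_, n)
    rows <- switch(spec$applies_to,
                   both = seq_len(n),
                   intersection = which(INT == 1L),
                   non_intersection = which(INT == 0L))
    col[rows] <- sample(spec$values, length(rows), replace = TRUE,
                        prob = config$marginals[[v]])
    data[[v]] <- col
  }
  data$SEV <- 1L + stats::rbinom(n, 1L, config$base_fatal_rate)
  planted_log <- list()
  planted_any <- logical(n)
  for (j in seq_along(config$planted)) {
    r <- config$planted[[j]]
    eligible <- switch(r$partition,
                       any = seq_len(n),
                       intersection = which(INT == 1L),
                       non_intersection = which(INT == 0L))
    np <- round(r$target_prevalence * n)
    if (np > length(eligible))
      stop("planted rule ", j, ": target prevalence exceeds its partition")
    ids <- sample(eligible, np)
    for (v in names(r$antecedent)) data[[v]][ids] <- r$antecedent[[v]]
    data$SEV[ids] <- 1L + stats::rbinom(np, 1L, r$fatal_probability)
    planted_any[ids] <- TRUE
    planted_log[[j]] <- list(
      antecedent = as.list(r$antecedent),
      partition = r$partition,
      fatal_probability = r$fatal_probability,
      target_prevalence = r$target_prevalence,
      rows = ids,
      realized_prevalence = np / n,
      realized_fatal_rate = mean(data$SEV[ids] == 2L))
  }
  realized_miss <- stats::setNames(numeric(0), character(0))
  for (v in names(config$missingness)) {
    f <- config$missingness[[v]]
    if (f <= 0) next
    rows <- which(!is.na(data[[v]]))
    mask <- rows[stats::rbinom(length(rows), 1L, f) == 1L]
    data[[v]][mask] <- NA_integer_
    realized_miss[v] <- length(mask) / length(rows)
  }
  data$INT <- INT
  ds <- accident_dataset(data, schema = schema, partition = "both")
  truth <- list(seed = config$seed, n_records = n,
                base_fatal_rate = config$base_fatal_rate,
                realized_base_fatal_rate = mean(data$SEV[!planted_any] == 2L),
                intersection_count = sum(INT == 1L),
                realized_missingness = as.list(realized_miss),
                planted = planted_log)
  list(dataset = ds, truth = truth)
}

#' Write a synthetic truth log as JSON
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_log <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.fixture_schema <- function(vars) {
  specs <- lapply(names(vars), function(v)
    variable_spec(v, vars[[v]], missing_allowed = TRUE))
  accident_schema(c(specs, list(variable_spec("SEV", 1:2,
                                              c("slight", "fatal")))))
}

#' Catalogued hand-built unit-test datasets
#'
#' Small fixed datasets used across the test suite:
#' \describe{
#'   \item{`"iig_negative"`}{10 records, class counts (8, 2); `X` balanced
#'     with per-branch class counts (4, 1) and (4, 1). Constructed so the
#'     imprecise info-gain of `X` (s = 1) is negative.}
#'   \item{`"pure_split"`}{10 records; `X1` copies the class exactly, `X2`
#'     is nearly independent of it.}
#'   \item{`"forced_root"`}{12 records; `X1` separates the classes
#'     perfectly, `X2` is pure noise. Forcing the root to `X2` must yield a
#'     depth-2 tree that splits on `X1` below and classifies perfectly.}
#'   \item{`"support_toy"`}{10 records over variables `A`, `B`; 4 records
#'     match `A = 1 & B = 1`, 3 of them fatal.}
#' }
#'
#' @param name Fixture name.
#' @return An `accident_dataset`.
#' @export
make_fixture <- function(name) {
  switch(name,
    iig_negative = {
      sch <- .fixture_schema(list(X = 1:2))
      accident_dataset(data.frame(
        X = rep(1:2, each = 5),
        SEV = rep(c(1L, 1L, 1L, 1L, 2L), 2)), schema = sch)
    },
    pure_split = {
      sch <- .fixture_schema(list(X1 = 1:2, X2 = 1:2))
      accident_dataset(data.frame(
        X1 = rep(1:2, each = 5),
        X2 = rep(1:2, 5),
        SEV = rep(1:2, each = 5)), schema = sch)
    },
    forced_root = {
      sch <- .fixture_schema(list(X1 = 1:2, X2 = 1:2))
      accident_dataset(data.frame(
        X1 = rep(rep(1:2, each = 3), 2),
        X2 = rep(1:2, each = 6),
        SEV = rep(rep(1:2, each = 3), 2)), schema = sch)
    },
    support_toy = {
      sch <- .fixture_schema(list(A = 1:2, B = 1:2))
      accident_dataset(data.frame(
        A   = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L, 2L),
        B   = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 1L, 2L, 2L),
        SEV = c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 2L, 1L, 1L)), schema = sch)
    },
    stop("unknown fixture '", name, "'")
  )
}
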