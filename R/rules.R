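# Decision-rule extraction from trees, support / probability scoring on the
# dataset, threshold selection with the fatal-consequent filter, and the
# delimited rule-table format (NR, A1..A4, Co, S, Pr).

# Internal rule representation: list(antecedent = named integer vector in
# path order, consequent = integer class). Canonical key sorts conditions by
# variable name so duplicates collapse regardless of path order.
.rule_key <- function(antecedent, consequent) {
  ord <- order(names(antecedent))
  paste0(paste(names(antecedent)[ord], antecedent[ord], sep = "=",
               collapse = " & "), " => ", consequent)
}

.rules_df <- function(rules) {
  if (length(rules) == 0L) {
    out <- data.frame(key = character(0), consequent = integer(0),
                      n_conditions = integer(0))
    out$antecedent <- list()
    class(out) <- c("decision_rules", "data.frame")
    return(out)
  }
  out <- data.frame(
    key = vapply(rules, function(r) .rule_key(r$antecedent, r$consequent),
                 character(1)),
    consequent = vapply(rules, function(r) as.integer(r$consequent), integer(1)),
    n_conditions = vapply(rules, function(r) length(r$antecedent), integer(1))
  )
  out$antecedent <- lapply(rules, function(r) r$antecedent)
  class(out) <- c("decision_rules", "data.frame")
  out
}

.dedup_rules <- function(rules) {
  keep <- !duplicated(rules$key)
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("decision_rules", "data.frame")
  out
}

#' @export
print.decision_rules <- function(x, n = 10L, ...) {
  cat(sprintf("decision_rules: %d rule(s)%s\n", nrow(x),
              if ("probability" %in% names(x)) " (scored)" else ""))
  for (i in seq_len(min(n, nrow(x)))) {
    cat("  IF ", paste(names(x$antecedent[[i]]), x$antecedent[[i]],
                       sep = " = ", collapse = " AND "),
        " THEN ", x$consequent[i], sep = "")
    if ("probability" %in% names(x))
      cat(sprintf("  [S=%.4f%%, Pr=%.2f%%]",
                  100 * x$support[i], 100 * x$probability[i]))
    cat("\n")
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Extract decision rules from a tree
#'
#' One IF-THEN rule per leaf: the antecedent collects the
#' `variable = value` conditions on the root-to-leaf path, the consequent is
#' the leaf's majority class. A single-leaf (or empty-marker) tree yields no
#' rules.
#'
#' @param tree A `credal_tree`.
#' @return A list of rules, each `list(antecedent, consequent)` with the
#'   antecedent a named integer vector in path order.
#' @export
extract_rules <- function(tree) {
  if (isTRUE(attr(tree, "empty")) || is.null(tree$var)) return(list())
  out <- list()
  rec <- function(node, path) {
    if (is.null(node$var)) {
      out[[length(out) + 1L]] <<- list(antecedent = path,
                                       consequent = node$leaf_class)
      return(invisible(NULL))
    }
    for (v in names(node$branches)) {
      cond <- stats::setNames(as.integer(v), node$var)
      rec(node$branches[[v]], c(path, cond))
    }
  }
  rec(tree, stats::setNames(integer(0), character(0)))
  out
}

.match_antecedent <- function(ds, antecedent) {
  m <- rep(TRUE, nrow(ds$data))
  for (v in names(antecedent)) {
    x <- ds$data[[v]]
    if (is.null(x)) return(rep(FALSE, nrow(ds$data)))
    m <- m & !is.na(x) & x == antecedent[[v]]
  }
  m
}

#' Support of a rule on a dataset
#'
#' The fraction of all records where the antecedent and the consequent are
#' simultaneously present. A record matches a condition only when the
#' variable is observed and equal; records are counted with unit weight.
#'
#' @param rule `list(antecedent = named codes, consequent = class)`.
#' @param ds An `accident_dataset`.
#' @return Support fraction in `[0, 1]`.
#' @export
compute_support <- function(rule, ds) {
  if (nrow(ds$data) == 0L) stop("empty dataset; support undefined")
  m <- .match_antecedent(ds, rule$antecedent)
  sum(m & ds$data$SEV == rule$consequent) / nrow(ds$data)
}

#' Probability (confidence) of a rule on a dataset
#'
#' `Pr = P(consequent | antecedent) = P(A, B) / P(A)` on the same unit-weight
#' matching convention as [compute_support()]. Undefined (error) when no
#' record matches the antecedent.
#'
#' @inheritParams compute_support
#' @return Probability fraction in `[0, 1]`.
#' @export
compute_probability <- function(rule, ds) {
  m <- .match_antecedent(ds, rule$antecedent)
  nA <- sum(m)
  if (nA == 0L) stop("no record matches the antecedent; probability undefined")
  sum(m & ds$data$SEV == rule$consequent) / nA
}

#' Score a rule set on a dataset
#'
#' Adds `support`, `probability` and `n_antecedent_matches` columns. Rules
#' whose antecedent matches no record get `NA` probability.
#'
#' @param rules A `decision_rules` data.frame.
#' @param ds An `accident_dataset`.
#' @return The scored `decision_rules`.
#' @export
score_rules <- function(rules, ds) {
  n <- nrow(ds$data)
  if (n == 0L) stop("empty dataset; scores undefined")
  nA <- integer(nrow(rules)); nAB <- integer(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    m <- .match_antecedent(ds, rules$antecedent[[i]])
    nA[i] <- sum(m)
    nAB[i] <- sum(m & ds$data$SEV == rules$consequent[i])
  }
  rules$support <- nAB / n
  rules$probability <- ifelse(nA > 0, nAB / nA, NA_real_)
  rules$n_antecedent_matches <- nA
  class(rules) <- c("decision_rules", "data.frame")
  rules
}

#' Rule-selection thresholds
#'
#' Defaults follow the imbalanced-data setting: minimum probability 10%,
#' minimum support 0.1%, and only rules whose consequent is the fatal class
#' are kept.
#'
#' @param min_probability Minimum `Pr`, in `(0, 1)`.
#' @param min_support Minimum `S`, in `(0, 1)`.
#' @param consequent_filter Class the consequent must equal (default 2,
#'   fatal), or `NA` to keep all consequents.
#' @return A `selection_thresholds` list.
#' @export
selection_thresholds <- function(min_probability = 0.10, min_support = 0.001,
                                 consequent_filter = 2L) {
  stopifnot(min_probability > 0, min_probability < 1,
            min_support > 0, min_support < 1)
  structure(list(min_probability = min_probability, min_support = min_support,
                 consequent_filter = consequent_filter),
            class = "selection_thresholds")
}

#' Select, deduplicate and sort decision rules
#'
#' Scores the rules on the dataset (unless they already carry `support` and
#' `probability` and `ds` is `NULL`), keeps those with the configured
#' consequent, `Pr >= min_probability` and `S >= min_support`, drops rules
#' whose antecedent matches no record, collapses duplicates (same antecedent
#' set and consequent), and sorts by probability descending, ties by support
#' descending then antecedent lexicographic order. Idempotent.
#'
#' @param rules A `decision_rules` data.frame.
#' @param ds An `accident_dataset`, or `NULL` to filter already-scored rules.
#' @param thresholds A [selection_thresholds()].
#' @return The selected, scored, sorted `decision_rules`.
#' @export
select_rules <- function(rules, ds = NULL,
                         thresholds = selection_thresholds()) {
  if (!is.null(ds)) {
    # the consequent filter commutes with scoring; apply it first
    if (!is.na(thresholds$consequent_filter)) {
      rules <- rules[rules$consequent == thresholds$consequent_filter, ,
                     drop = FALSE]
      class(rules) <- c("decision_rules", "data.frame")
    }
    rules <- score_rules(rules, ds)
  } else if (!all(c("support", "probability") %in% names(rules))) {
    stop("rules are unscored; supply the dataset")
  }
  rules <- .dedup_rules(rules)
  keep <- !is.na(rules$probability) &
    rules$probability >= thresholds$min_probability &
    rules$support >= thresholds$min_support
  if (!is.na(thresholds$consequent_filter))
    keep <- keep & rules$consequent == thresholds$consequent_filter
  out <- rules[keep, , drop = FALSE]
  ord <- order(-out$probability, -out$support, out$key)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("decision_rules", "data.frame")
  out
}

.fmt_pct <- function(x) {
  s <- sprintf("%.4f", 100 * x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  paste0(s, "%")
}

#' Write a rule table as delimited text
#'
#' Tab-separated columns `NR`, `A1`..`A4` (conditions `VAR = value`, blank
#' when the antecedent is shorter), `Co` (`FI` fatal / `SI` slight), `S` and
#' `Pr` as percentages.
#'
#' @param rules A scored `decision_rules`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(rules, path) {
  stopifnot(all(c("support", "probability") %in% names(rules)))
  amat <- t(vapply(seq_len(nrow(rules)), function(i) {
    a <- rules$antecedent[[i]]
    conds <- paste(names(a), a, sep = " = ")
    length(conds) <- 4L
    ifelse(is.na(conds), "", conds)
  }, character(4)))
  if (nrow(rules) == 0L) amat <- matrix(character(0), 0, 4)
  tab <- data.frame(NR = seq_len(nrow(rules)),
                    A1 = amat[, 1], A2 = amat[, 2], A3 = amat[, 3],
                    A4 = amat[, 4],
                    Co = ifelse(rules$consequent == 2L, "FI", "SI"),
                    S = vapply(rules$support, .fmt_pct, character(1)),
                    Pr = vapply(rules$probability, .fmt_pct, character(1)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rule table from delimited text
#'
#' Parses the format of [write_rule_table()] (percent signs in `S`/`Pr` are
#' optional) back into a scored `decision_rules` data.frame.
#'
#' @param path Input file path.
#' @return A scored `decision_rules`.
#' @export
read_rule_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  pct <- function(s) as.numeric(sub("%$", "", s)) / 100
  rules <- lapply(seq_len(nrow(tab)), function(i) {
    conds <- unlist(tab[i, c("A1", "A2", "A3", "A4")], use.names = FALSE)
    conds <- conds[!is.na(conds) & nzchar(trimws(conds))]
    parts <- strsplit(conds, "=")
    ant <- stats::setNames(
      vapply(parts, function(p) as.integer(trimws(p[2])), integer(1)),
      vapply(parts, function(p) trimws(p[1]), character(1)))
    list(antecedent = ant,
         consequent = if (trimws(tab$Co[i]) == "FI") 2L else 1L)
  })
  out <- .rules_df(rules)
  out$support <- pct(tab$S)
  out$probability <- pct(tab$Pr)
  class(out) <- c("decision_rules", "data.frame")
  out
}
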