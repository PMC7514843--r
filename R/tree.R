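# Depth-limited, unpruned decision trees with a forced root and C4.5-style
# fractional handling of missing values, plus the information-root-node-
# variation (IRNV) ensemble: one tree per candidate root per split criterion,
# all extracted rules pooled.

#' IRNV configuration
#'
#' @param criteria Subset of `c("IGR", "IIG", "ANPIM")` to run.
#' @param s IDM hyperparameter used by the IIG criterion (default 1).
#' @param max_depth Maximum number of split nodes on any root-to-leaf path
#'   (default 4, so extracted rules carry at most four conditions).
#' @param min_leaf_weight A split is admissible only when at least two
#'   branches receive this much (possibly fractional) instance weight
#'   (default 2, the J48 convention).
#' @param seed Optional integer recorded for provenance; tree induction
#'   itself is deterministic.
#' @return An `irnv_config` list.
#' @export
irnv_config <- function(criteria = c("IGR", "IIG", "ANPIM"), s = 1,
                        max_depth = 4, min_leaf_weight = 2, seed = NULL) {
  criteria <- match.arg(criteria, c("IGR", "IIG", "ANPIM"), several.ok = TRUE)
  stopifnot(max_depth >= 1, min_leaf_weight >= 1, s > 0)
  structure(list(criteria = criteria, s = s, max_depth = as.integer(max_depth),
                 min_leaf_weight = min_leaf_weight, seed = seed),
            class = "irnv_config")
}

# Majority class of a named class-count vector; ties break toward the first
# class level (the global majority class, slight injury).
.majority <- function(counts, class_levels) {
  class_levels[which.max(counts)]
}

.leaf <- function(counts, class_levels, depth, weight) {
  list(var = NULL, branches = NULL, branch_share = NULL,
       counts = counts, weight = weight, depth = depth,
       leaf_class = .majority(counts, class_levels))
}

.class_counts <- function(y, w, class_levels) {
  as.numeric(colSums(outer(y, class_levels, `==`) * w))
}

# Recursive node builder over row indices and fractional weights.
# forced: variable name to split on regardless of its score (the root);
# otherwise the best admissible unused variable with score > 0 is chosen.
.grow <- function(cols, y, w_all, idx, w, avail, depth, forced,
                  criterion, config, class_levels) {
  yn <- y[idx]
  binary <- length(class_levels) == 2L
  if (binary) {
    w1 <- w * (yn == class_levels[1]); w2 <- w * (yn == class_levels[2])
    counts <- c(sum(w1), sum(w2))
  } else {
    counts <- .class_counts(yn, w, class_levels)
  }
  weight <- sum(w)
  node <- .leaf(counts, class_levels, depth, weight)
  if (!is.null(forced)) {
    pick <- forced  # IRNV forces the root split even when uninformative
  } else {
    if (depth >= config$max_depth) return(node)
    if (sum(counts > 0) <= 1L) return(node)  # pure node
    if (length(avail) == 0L) return(node)
    pick <- NULL
    best <- -Inf
    for (v in avail) {
      if (binary) {
        ev <- .split_eval2(cols[[v]][idx], w1, w2, criterion, config$s,
                           config$min_leaf_weight)
        if (is.na(ev$score) || ev$score <= 0 || ev$score <= best || !ev$ok)
          next
        best <- ev$score; pick <- v
      } else {
        sc <- .crit_value(cols[[v]][idx], yn, w, criterion, config$s,
                          class_levels)
        if (is.na(sc) || sc <= 0 || sc <= best) next
        if (!.admissible(cols[[v]][idx], w, config$min_leaf_weight)) next
        best <- sc; pick <- v
      }
    }
    if (is.null(pick)) return(node)
  }
  x <- cols[[pick]][idx]
  obs <- !is.na(x)
  if (!any(obs)) return(node)
  bw <- rowsum(w[obs], group = x[obs], reorder = TRUE)
  vals <- as.integer(rownames(bw))
  bw <- as.numeric(bw)
  if (length(vals) < 2L) return(node)  # constant split variable -> leaf
  if (is.null(forced) && sum(bw >= config$min_leaf_weight) < 2L) return(node)
  share <- bw / sum(bw)
  avail2 <- setdiff(avail, pick)
  branches <- vector("list", length(vals))
  names(branches) <- as.character(vals)
  midx <- idx[!obs]; mw <- w[!obs]
  for (b in seq_along(vals)) {
    sel <- obs & x == vals[b]
    bidx <- c(idx[sel], midx)
    bwts <- c(w[sel], mw * share[b])
    branches[[b]] <- .grow(cols, y, w_all, bidx, bwts, avail2, depth + 1L,
                           NULL, criterion, config, class_levels)
  }
  node$var <- pick
  node$branches <- branches
  node$branch_share <- stats::setNames(share, as.character(vals))
  node$leaf_class <- .majority(counts, class_levels)
  node
}

# Admissibility of a candidate split: at least two branches of observed
# weight >= min_leaf_weight.
.admissible <- function(x, w, min_leaf_weight) {
  obs <- !is.na(x)
  if (!any(obs)) return(FALSE)
  bw <- rowsum(w[obs], group = x[obs])
  sum(bw >= min_leaf_weight) >= 2L
}

#' Build a decision tree with a forced root variable
#'
#' Grows an unpruned, depth-limited tree: the root splits on `root_variable`;
#' every node below splits on the unused variable maximizing the split
#' criterion, but only while the score is strictly positive, the depth limit
#' is not reached, and at least two branches would receive
#' `min_leaf_weight` of instance weight. Leaves carry the majority class of
#' their weighted partition. An instance missing the split variable descends
#' every branch with its weight scaled by the branch's share of observed
#' weight (the C4.5 convention); criterion scores under missing values are
#' computed on observed weight and scaled by the observed fraction.
#'
#' For the imprecise criteria (`IIG`, `ANPIM`) a strictly negative criterion
#' value of the forced root on the full dataset vetoes the whole tree: an
#' empty-tree marker is returned and contributes no rules.
#'
#' @param ds An `accident_dataset`.
#' @param root_variable Predictor forced at the root.
#' @param criterion `"IGR"`, `"IIG"` or `"ANPIM"`.
#' @param config An [irnv_config()].
#' @return A `credal_tree` (nested-list nodes), or an empty-tree marker with
#'   attribute `empty = TRUE`.
#' @export
build_tree <- function(ds, root_variable, criterion = "IGR",
                       config = irnv_config()) {
  criterion <- match.arg(criterion, c("IGR", "IIG", "ANPIM"))
  stopifnot(inherits(ds, "accident_dataset"))
  preds <- schema_predictors(ds$schema, ds$partition)
  if (!root_variable %in% preds)
    stop("'", root_variable, "' is not a predictor of this dataset")
  class_levels <- ds$schema$SEV$values
  y <- ds$data$SEV
  w <- ds$weights
  cols <- ds$data[preds]
  if (criterion %in% c("IIG", "ANPIM")) {
    sc <- .crit_value(cols[[root_variable]], y, w, criterion, config$s,
                      class_levels)
    if (!is.na(sc) && sc < 0) {
      return(structure(list(var = NULL, counts = .class_counts(y, w, class_levels),
                            weight = sum(w), depth = 0L,
                            leaf_class = .majority(
                              .class_counts(y, w, class_levels), class_levels)),
                       class = "credal_tree", empty = TRUE,
                       criterion = criterion, root = root_variable))
    }
  }
  root <- .grow(cols, y, w, seq_along(y), w, preds, 0L, root_variable,
                criterion, config, class_levels)
  structure(root, class = "credal_tree", empty = FALSE,
            criterion = criterion, root = root_variable,
            class_levels = class_levels)
}

#' @export
print.credal_tree <- function(x, ...) {
  if (isTRUE(attr(x, "empty"))) {
    cat(sprintf("credal_tree [%s, root %s]: empty (negative criterion at root)\n",
                attr(x, "criterion"), attr(x, "root")))
    return(invisible(x))
  }
  cat(sprintf("credal_tree [%s, root %s]\n", attr(x, "criterion"), attr(x, "root")))
  rec <- function(node, prefix, label) {
    cat(prefix, label,
        sprintf("[%s] w=%.2f -> %d\n",
                paste(format(node$counts, digits = 4), collapse = "/"),
                node$weight, node$leaf_class))
    if (!is.null(node$var)) {
      for (v in names(node$branches))
        rec(node$branches[[v]], paste0(prefix, "  "),
            sprintf("%s = %s ", node$var, v))
    }
  }
  rec(x, "", "")
  invisible(x)
}

# Aggregated class-mass vector for a record: missing split values distribute
# the record across branches by training weight share; a value unseen in
# training falls back to the node's own class proportions.
.class_mass <- function(node, record) {
  if (is.null(node$var)) return(node$counts / max(node$weight, .Machine$double.eps))
  v <- record[[node$var]]
  if (is.null(v) || is.na(v)) {
    m <- 0
    for (b in names(node$branches))
      m <- m + node$branch_share[[b]] * .class_mass(node$branches[[b]], record)
    return(m)
  }
  b <- as.character(v)
  if (!b %in% names(node$branches))
    return(node$counts / max(node$weight, .Machine$double.eps))
  .class_mass(node$branches[[b]], record)
}

#' Classify a record with a decision tree
#'
#' Follows the branch matching each split value. A record missing a split
#' value is distributed across all branches by the branches' training weight
#' shares, and the class with maximal aggregated class-count mass is
#' returned; a value unseen at training time falls back to the node's
#' majority class.
#'
#' @param tree A `credal_tree`.
#' @param record Named list or vector of codes (NA = missing).
#' @return Severity class code.
#' @export
classify_instance <- function(tree, record) {
  levels <- attr(tree, "class_levels")
  if (is.null(levels)) levels <- seq_along(tree$counts)
  mass <- .class_mass(tree, as.list(record))
  levels[which.max(mass)]
}

#' Rank predictors by a split criterion on the full dataset
#'
#' Variables are scored on the whole dataset and sorted by descending
#' criterion value; ties break by schema column order. Variables with an
#' undefined score (constant or entirely missing) are appended after the
#' ranked ones; if no variable has a defined score the ranking is empty.
#'
#' @param ds An `accident_dataset`.
#' @param criterion `"IGR"`, `"IIG"` or `"ANPIM"`.
#' @param s IDM hyperparameter for `"IIG"`.
#' @return A data.frame with columns `variable` and `score` (NA when
#'   undefined), in ranking order.
#' @export
rank_variables <- function(ds, criterion = "IGR", s = 1) {
  criterion <- match.arg(criterion, c("IGR", "IIG", "ANPIM"))
  preds <- schema_predictors(ds$schema, ds$partition)
  y <- ds$data$SEV; w <- ds$weights
  levels <- ds$schema$SEV$values
  scores <- vapply(preds, function(v)
    .crit_value(ds$data[[v]], y, w, criterion, s, levels), numeric(1))
  if (all(is.na(scores)))
    return(data.frame(variable = character(0), score = numeric(0)))
  ord <- order(ifelse(is.na(scores), -Inf, scores), decreasing = TRUE)
  out <- data.frame(variable = preds[ord], score = scores[ord],
                    row.names = NULL)
  # stable: order() above is stable in schema order for ties
  out
}

#' Run the information-root-node-variation ensemble
#'
#' For each configured split criterion, the predictors are ranked on the full
#' dataset and one tree is built per predictor with that predictor forced as
#' the root. All rules extracted from all trees are pooled and deduplicated
#' (same antecedent set and consequent appear once). For the imprecise
#' criteria, a root variable whose criterion value on the full dataset is
#' negative contributes an empty rule set.
#'
#' @param ds An `accident_dataset`.
#' @param config An [irnv_config()].
#' @return A `decision_rules` data.frame (unscored) with attributes
#'   `n_trees`, `n_rules_raw` and `per_criterion` (trees and rules per
#'   criterion).
#' @export
run_irnv <- function(ds, config = irnv_config()) {
  stopifnot(inherits(ds, "accident_dataset"))
  all_rules <- list()
  n_trees <- 0L
  n_raw <- 0L
  per_criterion <- list()
  for (crit in config$criteria) {
    ranking <- rank_variables(ds, crit, s = config$s)
    ct <- 0L; cr <- 0L
    for (i in seq_len(nrow(ranking))) {
      v <- ranking$variable[i]
      sc <- ranking$score[i]
      if (crit %in% c("IIG", "ANPIM") && !is.na(sc) && sc < 0) next
      tree <- build_tree(ds, v, crit, config)
      n_trees <- n_trees + 1L; ct <- ct + 1L
      rules <- extract_rules(tree)
      cr <- cr + length(rules)
      all_rules <- c(all_rules, rules)
    }
    per_criterion[[crit]] <- c(trees = ct, rules = cr)
    n_raw <- n_raw + cr
  }
  out <- .rules_df(all_rules)
  out <- .dedup_rules(out)
  attr(out, "n_trees") <- n_trees
  attr(out, "n_rules_raw") <- n_raw
  attr(out, "per_criterion") <- per_criterion
  out
}
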