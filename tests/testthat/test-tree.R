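test_that("variable ranking puts the informative predictor first under all criteria", {
  ps <- make_fixture("pure_split")
  for (crit in c("IGR", "IIG", "ANPIM")) {
    rk <- rank_variables(ps, crit)
    expect_identical(rk$variable[1], "X1")
  }
  # all-constant predictors: nothing rankable
  sch <- accident_schema(list(variable_spec("X1", 1:2), variable_spec("X2", 1:2),
                              variable_spec("SEV", 1:2)))
  cds <- accident_dataset(data.frame(X1 = 1L, X2 = 2L, SEV = rep(1:2, 4)),
                          schema = sch, validate = FALSE)
  expect_identical(nrow(rank_variables(cds, "IGR")), 0L)
})

test_that("a forced uninformative root still yields a perfectly classifying subtree", {
  fr <- make_fixture("forced_root")
  tr <- build_tree(fr, "X2", "IGR")
  expect_identical(tr$var, "X2")
  expect_identical(tree_depth(tr), 2L)
  for (b in tr$branches) expect_identical(b$var, "X1")
  for (i in seq_len(nrow(fr$data))) {
    expect_identical(classify_instance(tr, fr$data[i, c("X1", "X2")]),
                     fr$data$SEV[i])
  }
  rules <- extract_rules(tr)
  expect_length(rules, 4L)
  expect_true(all(vapply(rules, function(r) length(r$antecedent), integer(1)) == 2L))
})

test_that("a pure dataset and a constant root both stop immediately below the root", {
  sch <- accident_schema(list(variable_spec("X", 1:2), variable_spec("SEV", 1:2)))
  pure <- accident_dataset(data.frame(X = rep(1:2, 4), SEV = rep(1L, 8)),
                           schema = sch, validate = FALSE)
  tr <- build_tree(pure, "X", "IGR")
  expect_identical(tr$var, "X")
  for (b in tr$branches) {
    expect_null(b$var)
    expect_identical(b$leaf_class, 1L)
  }
  const <- accident_dataset(data.frame(X = rep(1L, 8), SEV = rep(1:2, 4)),
                            schema = sch, validate = FALSE)
  stump <- build_tree(const, "X", "IGR")
  expect_null(stump$var)  # single-leaf tree
  expect_length(extract_rules(stump), 0L)
})

test_that("a negative imprecise criterion at the forced root vetoes the tree", {
  fx <- make_fixture("iig_negative")
  tr <- build_tree(fx, "X", "IIG")
  expect_true(attr(tr, "empty"))
  expect_length(extract_rules(tr), 0L)
  # the same root under the precise criterion is simply forced
  tr2 <- build_tree(fx, "X", "IGR")
  expect_identical(tr2$var, "X")
})

test_that("classification aggregates over branches when the split value is missing", {
  sch <- accident_schema(list(variable_spec("X", 1:2, missing_allowed = TRUE),
                              variable_spec("SEV", 1:2)))
  ds <- accident_dataset(data.frame(X = c(rep(1L, 7), rep(2L, 3)),
                                    SEV = c(rep(1L, 7), rep(2L, 3))),
                         schema = sch)
  tr <- build_tree(ds, "X", "IGR")
  # heavier subtree (7 slight) wins for a missing split value
  expect_identical(classify_instance(tr, list(X = NA)), 1L)
  expect_identical(classify_instance(tr, list(X = 2L)), 2L)
  # single-leaf tree returns its majority class regardless of the record
  stump <- build_tree(accident_dataset(data.frame(X = 1L, SEV = rep(c(1L, 1L, 2L), 3)),
                                       schema = sch, validate = FALSE),
                      "X", "IGR")
  expect_identical(classify_instance(stump, list(X = 2L)), 1L)
})

test_that("trees respect the depth cap, conserve fractional weight, and never reuse a path variable", {
  gen <- generate_dataset(synthetic_config(n_records = 2500, seed = 31))
  ds <- split_by_intersection(gen$dataset)$intersection
  cfg <- irnv_config()
  no_repeat <- function(node, seen) {
    if (is.null(node$var)) return(TRUE)
    if (node$var %in% seen) return(FALSE)
    all(vapply(node$branches, no_repeat, logical(1), seen = c(seen, node$var)))
  }
  for (crit in c("IGR", "IIG")) {
    for (root in c("ACT_TY", "SP_IN", "RES_VIS")) {
      tr <- build_tree(ds, root, crit, cfg)
      if (isTRUE(attr(tr, "empty"))) next
      expect_lte(tree_depth(tr), cfg$max_depth)
      expect_equal(leaf_weight_sum(tr), sum(ds$weights), tolerance = 1e-6)
      expect_true(no_repeat(tr, character(0)))
      for (r in extract_rules(tr))
        expect_false(anyDuplicated(names(r$antecedent)) > 0)
    }
  }
})

test_that("the IRNV ensemble pools at most one tree per predictor per criterion and dedups rules", {
  ps <- make_fixture("pure_split")
  cfg <- irnv_config(criteria = c("IGR", "IIG", "ANPIM"))
  pooled <- run_irnv(ps, cfg)
  m <- length(schema_predictors(ps$schema))
  expect_lte(attr(pooled, "n_trees"), 3L * m)
  expect_false(anyDuplicated(pooled$key) > 0)
  # the X1 stump rules appear once though all three criteria produce them
  expect_true(any(pooled$key == "X1=2 => 2"))
  expect_identical(sum(pooled$key == "X1=2 => 2"), 1L)
  # negative-IIG roots contribute nothing
  fx <- make_fixture("iig_negative")
  pooled_iig <- run_irnv(fx, irnv_config(criteria = "IIG"))
  expect_identical(nrow(pooled_iig), 0L)
  expect_identical(attr(pooled_iig, "n_trees"), 0L)
})

test_that("tree induction is deterministic for a fixed dataset and configuration", {
  gen <- generate_dataset(synthetic_config(n_records = 1500, seed = 13))
  ds <- split_by_intersection(gen$dataset)$non_intersection
  a <- run_irnv(ds, irnv_config(criteria = c("IGR", "ANPIM")))
  b <- run_irnv(ds, irnv_config(criteria = c("IGR", "ANPIM")))
  expect_identical(a$key, b$key)
})
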