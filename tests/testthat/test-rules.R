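test_that("rule extraction yields one rule per leaf with path antecedents", {
  sch <- accident_schema(list(variable_spec("X", 1:2), variable_spec("SEV", 1:2)))
  ds <- accident_dataset(data.frame(X = rep(1:2, each = 4),
                                    SEV = rep(1:2, each = 4)), schema = sch)
  stump <- build_tree(ds, "X", "IGR")
  rules <- extract_rules(stump)
  expect_length(rules, 2L)
  expect_true(all(vapply(rules, function(r) length(r$antecedent), integer(1)) == 1L))
  expect_identical(rules[[1]]$antecedent, c(X = 1L))
  expect_identical(rules[[1]]$consequent, 1L)
})

test_that("support and probability follow the unit-weight matching convention", {
  toy <- make_fixture("support_toy")
  rule <- list(antecedent = c(A = 1L, B = 1L), consequent = 2L)
  expect_equal(compute_support(rule, toy), 0.30)
  expect_equal(compute_probability(rule, toy), 0.75)
  # empty dataset: support undefined
  empty <- accident_dataset(toy$data[0, ], schema = toy$schema)
  expect_error(compute_support(rule, empty), "empty")
  # antecedent matched by nobody: support 0, probability undefined
  toy0 <- toy
  toy0$data$A <- 2L
  expect_equal(compute_support(rule, toy0), 0)
  expect_error(compute_probability(rule, toy0), "no record")
  # a missing antecedent value never matches
  toy_na <- toy
  toy_na$data$A[1] <- NA
  expect_equal(compute_support(rule, toy_na), 0.20)
})

test_that("support is monotone non-increasing as antecedent conditions are added", {
  gen <- generate_dataset(synthetic_config(n_records = 800, seed = 23))
  ds <- split_by_intersection(gen$dataset)$intersection
  set.seed(23)
  preds <- schema_predictors(ds$schema, "intersection")
  for (i in 1:25) {
    vars <- sample(preds, 3)
    vals <- vapply(vars, function(v) sample(ds$schema[[v]]$values, 1), integer(1))
    names(vals) <- vars
    s2 <- compute_support(list(antecedent = vals[1:2], consequent = 2L), ds)
    s3 <- compute_support(list(antecedent = vals, consequent = 2L), ds)
    expect_lte(s3, s2)
    expect_lte(s2, compute_support(list(antecedent = vals[1], consequent = 2L), ds))
  }
})

test_that("threshold selection keeps the published boundary case and drops low support", {
  mk <- function(s, p, co = 2L) {
    r <- irnvrules:::.rules_df(list(list(antecedent = c(A = 1L, B = 1L),
                                         consequent = co)))
    r$support <- s; r$probability <- p
    r
  }
  th <- selection_thresholds()
  # S = 0.1033%, Pr = 68.8%: retained (the minimum-support published rule)
  expect_identical(nrow(select_rules(mk(0.001033, 0.688), thresholds = th)), 1L)
  # S = 0.05%, Pr = 90%: rejected on support despite high probability
  expect_identical(nrow(select_rules(mk(0.0005, 0.90), thresholds = th)), 0L)
  # Pr below 10%: rejected
  expect_identical(nrow(select_rules(mk(0.01, 0.09), thresholds = th)), 0L)
  # slight-injury consequent: rejected by the consequent filter
  expect_identical(nrow(select_rules(mk(0.01, 0.5, co = 1L), thresholds = th)),
                   0L)
})

test_that("every published rule of both study tables passes the selection filter", {
  for (f in c("published_rules_intersection.tsv",
              "published_rules_non_intersection.tsv")) {
    tab <- read_rule_table(system.file("extdata", f, package = "irnvrules",
                                       mustWork = TRUE))
    kept <- select_rules(tab, thresholds = selection_thresholds())
    expect_identical(nrow(kept), nrow(tab))
    expect_true(all(kept$probability >= kept$support))
    expect_true(all(vapply(kept$antecedent, length, integer(1)) %in% 1:4))
  }
})

test_that("selection is idempotent and sorted by probability then support", {
  run <- shared_planted_run()
  sel <- run$partitions$intersection$rules
  again <- select_rules(sel, thresholds = selection_thresholds())
  expect_identical(again$key, sel$key)
  expect_identical(again$probability, sel$probability)
  expect_true(all(diff(sel$probability) <= 1e-12))
  ties <- which(diff(sel$probability) == 0)
  if (length(ties)) expect_true(all(sel$support[ties] >= sel$support[ties + 1L]))
})

test_that("rule tables round-trip through the delimited format", {
  run <- shared_planted_run()
  sel <- run$partitions$intersection$rules
  expect_gt(nrow(sel), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rule_table(sel, path)
  back <- read_rule_table(path)
  expect_identical(back$key, sel$key)
  expect_equal(back$support, round(sel$support * 100, 4) / 100, tolerance = 1e-12)
  expect_equal(back$probability, round(sel$probability * 100, 4) / 100,
               tolerance = 1e-12)
})
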