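test_that("Shannon entropy matches direct evaluation and rejects non-distributions", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.25, 0.75)), 0.811278124459, tolerance = 1e-9)
  expect_error(shannon_entropy(c(0.5, 0.4)), "summing to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("conditional entropy weights branch entropies by branch probability", {
  expect_equal(conditional_entropy(make_fixture("pure_split"), "X1"), 0)
  # two balanced branches, each with class counts (4,1)
  fx <- make_fixture("iig_negative")
  expect_equal(conditional_entropy(fx, "X"),
               -(0.8 * log2(0.8) + 0.2 * log2(0.2)), tolerance = 1e-12)
  # an independent balanced predictor leaves a balanced class at 1 bit
  sch <- accident_schema(list(variable_spec("X", 1:2),
                              variable_spec("SEV", 1:2)))
  ds <- accident_dataset(data.frame(X = rep(1:2, 4),
                                    SEV = rep(1:2, each = 4)), schema = sch)
  expect_equal(conditional_entropy(ds, "X"), 1)
})

test_that("info-gain ratio handles perfect, independent and constant predictors", {
  ps <- make_fixture("pure_split")
  expect_equal(info_gain_ratio(ps, "X1")$value, 1)
  sch <- accident_schema(list(variable_spec("X", 1:2),
                              variable_spec("SEV", 1:2)))
  ds <- accident_dataset(data.frame(X = rep(1:2, 4),
                                    SEV = rep(1:2, each = 4)), schema = sch)
  expect_equal(info_gain_ratio(ds, "X")$value, 0)
  # class (8,2), X balanced with branch counts (4,1),(4,1): IG = 0
  expect_equal(info_gain_ratio(make_fixture("iig_negative"), "X")$value, 0,
               tolerance = 1e-12)
  # constant predictor: undefined, flagged for the caller to skip
  cds <- accident_dataset(data.frame(X = rep(1L, 8),
                                     SEV = rep(1:2, each = 4)), schema = sch,
                          validate = FALSE)
  expect_false(info_gain_ratio(cds, "X")$defined)
})

test_that("IDM and NPI intervals match their closed forms, clamps included", {
  iv <- idm_intervals(c(3, 6), s = 1)
  expect_equal(iv$lower, c(0.3, 0.6))
  expect_equal(iv$upper, c(0.4, 0.7))
  iv0 <- idm_intervals(c(0, 10), s = 1)
  expect_equal(iv0$lower, c(0, 10 / 11))
  expect_equal(iv0$upper, c(1 / 11, 1))
  # interval width is s/(N+s) for every class
  set.seed(3)
  for (i in 1:20) {
    counts <- stats::runif(sample(2:4, 1), 0, 9)
    s <- stats::runif(1, 0.5, 3)
    iv <- idm_intervals(counts, s)
    expect_equal(iv$upper - iv$lower,
                 rep(s / (sum(counts) + s), length(counts)))
  }
  nv <- anpim_intervals(c(3, 6))
  expect_equal(nv$lower, c(2 / 9, 5 / 9))
  expect_equal(nv$upper, c(4 / 9, 7 / 9))
  nv0 <- anpim_intervals(c(0, 9))
  expect_equal(nv0$lower, c(0, 8 / 9))
  expect_equal(nv0$upper, c(1 / 9, 1))
  expect_equal(anpim_intervals(c(9, 0))$upper[1], 1)  # clamped at 1
  expect_error(idm_intervals(c(0, 0)), "zero")
  expect_error(idm_intervals(c(1, 1), s = 0), "positive")
  expect_error(anpim_intervals(c(0, 0)), "zero")
})

test_that("water-filling maximum entropy matches frozen and oracle values", {
  me <- max_entropy_distribution(probability_intervals(c(0.3, 0.6), c(0.4, 0.7)))
  expect_equal(me$p, c(0.4, 0.6), tolerance = 1e-9)
  expect_equal(me$entropy, 0.970950594455, tolerance = 1e-9)
  # degenerate point set
  pt <- max_entropy_distribution(probability_intervals(c(0.2, 0.8), c(0.2, 0.8)))
  expect_equal(pt$p, c(0.2, 0.8), tolerance = 1e-9)
  # IDM box of counts (1,1,8): maximizer lifts the small classes evenly
  me3 <- max_entropy_distribution(idm_intervals(c(1, 1, 8), s = 1))
  expect_equal(me3$p, c(1.5, 1.5, 8) / 11, tolerance = 1e-9)
  expect_equal(me3$entropy, 1.118078, tolerance = 1e-5)
  or3 <- grid_max_entropy(c(1, 1, 8) / 11, c(2, 2, 9) / 11)
  expect_equal(me3$entropy, or3$entropy, tolerance = 1e-6)
  expect_error(probability_intervals(c(0.6, 0.6), c(0.7, 0.7)), "empty")
})

test_that("imprecise gains match the hand fixture and sign expectations", {
  fx <- make_fixture("iig_negative")
  # marginal H* (counts 8,2; s=1) vs branch-weighted H* (counts 4,1 twice)
  expect_equal(imprecise_gain(fx, "X", "IDM", s = 1)$value,
               0.845350936622 - 0.918295834054, tolerance = 1e-9)
  ps <- make_fixture("pure_split")
  expect_gt(imprecise_gain(ps, "X1", "IDM")$value, 0)
  expect_gt(imprecise_gain(ps, "X1", "NPI")$value, 0)
  # constant predictor: conditional term equals the marginal term
  sch <- accident_schema(list(variable_spec("X", 1:2),
                              variable_spec("SEV", 1:2)))
  cds <- accident_dataset(data.frame(X = rep(1L, 8),
                                     SEV = rep(1:2, each = 4)), schema = sch,
                          validate = FALSE)
  expect_equal(imprecise_gain(cds, "X", "IDM")$value, 0)
  expect_equal(imprecise_gain(cds, "X", "NPI")$value, 0)
})

test_that("the empirical distribution stays inside both credal sets, bounding H*", {
  set.seed(41)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    counts <- stats::runif(k, 0.1, 12)
    emp <- counts / sum(counts)
    for (make in list(function(c) idm_intervals(c, s = 1), anpim_intervals)) {
      iv <- make(counts)
      expect_true(all(emp >= iv$lower - 1e-12 & emp <= iv$upper + 1e-12))
      hs <- max_entropy_distribution(iv)$entropy
      expect_gte(hs, shannon_entropy(emp) - 1e-12)
      expect_lte(hs, log2(k) + 1e-12)
    }
  }
})

test_that("the imprecise gain collapses to the precise info-gain as s vanishes", {
  set.seed(17)
  for (i in 1:10) {
    ds <- random_weighted_dataset(n = 25L, t = sample(2:4, 1))
    ig <- precise_info_gain(ds, "X")
    iig <- imprecise_gain(ds, "X", "IDM", s = 1e-8)$value
    expect_lt(abs(iig - ig), 1e-6)
  }
})
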