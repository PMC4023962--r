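test_that("pair extraction finds derived clades with pure sisters", {
  tr <- ape::read.tree(text = "(((c4a:1,c4b:1):1,(c3a:1,c3b:1):1):1,c3o:3);")
  td <- tip_data(tr$tip.label, c(1, 1, 0, 0, 0), mode = "proportional")
  pr <- extract_pairs(tr, td)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$focal_richness, 2)
  expect_equal(pr$sister_richness, 2)
  expect_equal(attr(pr, "n_origins"), 1L)
  ## richness sums use assigned per-tip richness
  td2 <- tip_data(tr$tip.label, c(1, 1, 0, 0, 0), richness = c(5, 2, 1, 1, 9),
                  mode = "unresolved", f = 1)
  pr2 <- extract_pairs(tr, td2)
  expect_equal(pr2$focal_richness, 7)
  ## no derived tips at all
  td0 <- tip_data(tr$tip.label, 0, mode = "proportional")
  expect_error(extract_pairs(tr, td0), "no derived-state")
  ## sisters containing derived or unknown tips disqualify the pair
  td3 <- tip_data(tr$tip.label, c(1, 1, 0, NA, 0), mode = "proportional")
  expect_equal(nrow(extract_pairs(tr, td3)), 0L)
})

test_that("pair count matches a brute-force subtree scan on random trees", {
  set.seed(61)
  for (i in 1:8) {
    phy <- as_timetree(ape::rcoal(24))
    states <- setNames(sample(0:1, 24, replace = TRUE, prob = c(.6, .4)),
                       phy$tip.label)
    td <- tip_data(phy$tip.label, states[phy$tip.label],
                   mode = "proportional")
    got <- tryCatch(nrow(extract_pairs(phy, td)), error = function(e) 0L)
    expect_equal(got, sister_pairs_brute(phy, states))
  }
})

test_that("uniformly positive differences give the enumeration p-value", {
  d <- log(2:13) - log(1)   # 12 positive differences, no ties at zero
  st <- signed_rank_test(diffs = d)
  expect_equal(st$p_greater, 2^-12, tolerance = 1e-12)
  expect_equal(st$statistic, 12 * 13 / 2)
  expect_equal(st$method, "exact")
})

test_that("the test is symmetric and invariant to log base and rescaling", {
  d <- c(1.2, -0.4, 0.7, -2.1, 0.05, 1.4, -0.6)
  st <- signed_rank_test(diffs = d)
  st_neg <- signed_rank_test(diffs = -d)
  expect_equal(st$p_greater, st_neg$p_less)
  expect_equal(st$p_two_sided, st_neg$p_two_sided)
  ## mirror-image pairs: perfectly antisymmetric differences
  st_sym <- signed_rank_test(diffs = c(d, -d))
  expect_equal(st_sym$p_two_sided, 1, tolerance = 1e-12)
  ## invariance: scaling all richness multiplies differences by nothing,
  ## changing the log base scales them by a constant; ranks are identical
  pairs <- data.frame(focal_richness = c(12, 30, 7, 22),
                      sister_richness = c(5, 14, 9, 4))
  a <- signed_rank_test(pairs)
  b <- signed_rank_test(data.frame(focal_richness = pairs$focal_richness * 7,
                                   sister_richness = pairs$sister_richness * 7))
  c2 <- signed_rank_test(diffs = log2(pairs$focal_richness) -
                           log2(pairs$sister_richness))
  expect_identical(a$p_greater, b$p_greater)
  expect_identical(a$p_greater, c2$p_greater)
})

test_that("exact enumeration agrees with wilcox.test and its normal limit", {
  set.seed(67)
  for (i in 1:5) {
    d <- round(rnorm(12), 3)
    d <- d[d != 0]
    st <- signed_rank_test(diffs = d)
    ref <- suppressWarnings(stats::wilcox.test(d, alternative = "greater"))
    expect_equal(st$statistic, unname(ref$statistic))
    if (!any(duplicated(abs(d))))
      expect_equal(st$p_greater, ref$p.value, tolerance = 1e-10)
  }
  ## n = 20: exact within 0.01 of the continuity-corrected normal value
  d <- round(rnorm(20, 0.3), 3)
  exact <- signed_rank_test(diffs = d, exact_limit = 25)
  approx <- signed_rank_test(diffs = d, exact_limit = 5)
  expect_lt(abs(exact$p_greater - approx$p_greater), 0.01)
  expect_error(signed_rank_test(diffs = numeric(0)), "zero|one pair")
  expect_error(signed_rank_test(diffs = c(0, 0)), "all differences")
})

test_that("the wrapper runs extraction and test together", {
  tr <- ape::read.tree(text = paste0(
    "((((c4a:1,c4b:1):1,c3a:2):1,((c4c:1.5,c4d:1.5):1,c3b:2.5):0.5):1,",
    "c3o:4.5);"))
  td <- tip_data(tr$tip.label, c(1, 1, 0, 1, 1, 0, 0),
                 richness = c(9, 4, 2, 11, 2, 3, 1), mode = "unresolved",
                 f = 1)
  out <- sister_contrasts(tr, td)
  expect_equal(nrow(out$pairs), 2L)
  expect_true(out$test$p_greater <= 1 && out$test$p_greater >= 0)
})
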