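test_that("richness likelihood matches its closed forms", {
  ## pure birth: P(1 | t) = e^{-lambda t}
  expect_equal(richness_loglik(1, 10, bd_regime(0.1, 0)), -1, tolerance = 1e-12)
  ## certain outcome as t -> 0
  expect_equal(richness_loglik(1, 1e-12, bd_regime(0.2, 0.4)), 0,
               tolerance = 1e-9)
  ## geometric partial sums approach 1
  reg <- bd_regime(0.15, 0.6)
  probs <- exp(richness_loglik(1:4000, 12, reg))
  b <- (exp(reg$r * 12) - 1) / (exp(reg$r * 12) - reg$eps)
  expect_equal(cumsum(probs)[c(10, 100, 4000)],
               1 - b^c(10, 100, 4000), tolerance = 1e-9)
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  ## monotone decreasing in lambda for a childless lineage
  lams <- seq(0.05, 1, by = 0.05)
  vals <- vapply(lams, function(l) richness_loglik(1, 5, bd_regime(l, 0)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("Yule sufficient-statistic identity holds on a fixed fixture", {
  set.seed(99)
  phy <- as_timetree(ape::rcoal(20))
  events <- ape::Ntip(phy) - 2          # non-root internal nodes
  lam_hat <- events / sum(phy$edge.length)
  prof <- function(l) backbone_loglik(phy, bd_regime(l, 0), condition = TRUE)
  opt <- stats::optimize(prof, c(lam_hat / 10, lam_hat * 10), maximum = TRUE,
                         tol = 1e-12)
  expect_equal(opt$maximum, lam_hat, tolerance = 1e-6)
})

test_that("single-regime recovery is unbiased on constant-rate trees", {
  set.seed(123)
  r_true <- 0.12; eps_true <- 0.5
  est <- replicate(40, {
    s <- simulate_piecewise_bd(bd_regime(r_true, eps_true), max_age = 45)
    f <- fit_shift_model(s$tree)
    c(f$regimes$r, f$regimes$eps)
  })
  r_mean <- mean(est[1, ]); r_se <- sd(est[1, ]) / sqrt(ncol(est))
  expect_lt(abs(r_mean - r_true), 4 * r_se + 0.01)
  expect_lt(abs(median(est[2, ]) - eps_true), 0.2)
})

test_that("adding shifts never lowers the total log-likelihood", {
  set.seed(125)
  s <- simulate_piecewise_bd(bd_regime(0.1, 0.3), max_age = 40)
  base <- fit_shift_model(s$tree)
  ne <- nrow(s$tree$edge)
  for (e in sample(seq_len(ne), 12)) {
    m <- tryCatch(fit_shift_model(s$tree, shifts = e), error = function(x) NULL)
    if (is.null(m)) next   # degenerate split (whole-regime takeover)
    expect_gte(m$lnL, base$lnL - 1e-4)
    expect_equal(m$k, 5L)
    expect_equal(m$n_obs, s$tree$Nnode + ape::Ntip(s$tree))
  }
})

test_that("a planted tenfold-faster subclade raises the likelihood at its stem", {
  ps <- simulate_piecewise_bd(bd_regime(0.05, 0.3), max_age = 60,
                              shift_regime = bd_regime(0.5, 0.3),
                              shift_age = 8, min_shift_tips = 15, seed = 31)
  base <- fit_shift_model(ps$tree)
  planted <- fit_shift_model(ps$tree, shifts = ps$shift_edge)
  expect_gt(planted$lnL, base$lnL + 5)
  expect_gt(planted$regimes$r[2], planted$regimes$r[1])
})

test_that("stepwise search honours the threshold and reports its steps", {
  ps <- simulate_piecewise_bd(bd_regime(0.05, 0.3), max_age = 60,
                              shift_regime = bd_regime(0.5, 0.3),
                              shift_age = 8, min_shift_tips = 15, seed = 31)
  sr <- stepwise_search(ps$tree, threshold = 10.5, max_shifts = 4)
  expect_gte(length(sr$model$shift_edges), 1L)
  acc <- sr$steps[sr$steps$accepted & sr$steps$step > 0, ]
  expect_true(all(acc$improvement >= 10.5))
  expect_true(all(diff(sr$steps$lnL) > -1e-6))
  ## an infinite threshold accepts nothing
  sr_inf <- stepwise_search(ps$tree, threshold = Inf)
  expect_length(sr_inf$model$shift_edges, 0L)
  tab <- shift_table(sr)
  expect_true(all(c("regime", "clade", "stem_age", "crown_age", "r", "eps")
                  %in% names(tab)))
  expect_error(stepwise_search(ps$tree, threshold = -1), "> 0")
})

test_that("richness data enter the shift model through stem ages", {
  set.seed(140)
  sim <- simulate_bisse_tree(bisse_params(.25, .25, .05, .05, 0, 0),
                             max_age = 12, seed = 140)
  col <- collapse_simulated_genera(sim$tree, sim$tips, block_cap = 4)
  m <- fit_shift_model(col$tree, richness = col$richness)
  expect_equal(m$n_obs, col$tree$Nnode + ape::Ntip(col$tree))
  expect_true(is.finite(m$AICc))
  ## richness-weighted fit sees more species than the backbone alone
  m_tipsonly <- fit_shift_model(col$tree)
  expect_false(isTRUE(all.equal(m$regimes$r, m_tipsonly$regimes$r)))
})
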