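test_that("simulation is byte-identical under a fixed seed", {
  p <- bisse_params(.3, .4, .1, .1, .05, .05)
  a <- simulate_bisse_tree(p, max_tips = 60, seed = 17)
  b <- simulate_bisse_tree(p, max_tips = 60, seed = 17)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$tips, b$tips)
  c <- simulate_bisse_tree(p, max_tips = 60, seed = 18)
  expect_false(identical(ape::write.tree(a$tree), ape::write.tree(c$tree)))
})

test_that("simulated trees pass ultrametricity validation", {
  set.seed(19)
  for (i in 1:4) {
    s <- simulate_bisse_tree(bisse_params(.3, .3, .1, .1, .04, .04),
                             max_age = 14)
    expect_silent(as_timetree(s$tree))
    expect_equal(root_age(s$tree), 14, tolerance = 1e-6)
  }
  s2 <- simulate_bisse_tree(bisse_params(.3, .3, .1, .1, .04, .04),
                            max_tips = 50, seed = 20)
  expect_equal(ape::Ntip(s2$tree), 50)
  expect_silent(as_timetree(s2$tree))
})

test_that("state 0 is absorbing when no transitions are allowed", {
  s <- simulate_bisse_tree(bisse_params(.4, .4, .05, .05, 0, 0),
                           max_tips = 40, root_state = 0, seed = 23)
  expect_true(all(s$tips$state == 0))
  s1 <- simulate_bisse_tree(bisse_params(.4, .4, .05, .05, 0, 0),
                            max_tips = 40, root_state = 1, seed = 23)
  expect_true(all(s1$tips$state == 1))
})

test_that("pure-birth tip counts match the branching-process expectation", {
  set.seed(29)
  lambda <- 0.25; t_run <- 6
  n <- replicate(600, {
    s <- simulate_bisse_tree(bisse_params(lambda, lambda, 0, 0, 0, 0),
                             max_age = t_run)
    ape::Ntip(s$tree)
  })
  expected <- 2 * exp(lambda * t_run)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 4 * se)
})

test_that("a higher derived-state speciation rate enriches derived tips", {
  set.seed(37)
  ## paired against a neutral run with the same transition scheme
  wins <- replicate(40, {
    f1 <- mean(simulate_bisse_tree(bisse_params(.15, .3, 0, 0, .05, .05),
                                   max_age = 20)$tips$state == 1)
    f0 <- mean(simulate_bisse_tree(bisse_params(.15, .15, 0, 0, .05, .05),
                                   max_age = 20)$tips$state == 1)
    f1 - f0
  })
  ## sign test: the state-dependent runs carry more derived tips
  expect_gt(mean(wins > 0), 0.7)
})

test_that("Bernoulli subsampling keeps roughly f of the tips", {
  set.seed(41)
  s <- simulate_bisse_tree(bisse_params(.4, .4, .1, .1, .02, .02),
                           max_age = 14, f = 0.5)
  expect_equal(attr(s$tips, "f"), 0.5)
  expect_lt(ape::Ntip(s$tree), 200)  # sanity: subsampled tree is not huge
})

test_that("the no-shift piecewise simulator matches the constant-rate one", {
  set.seed(43)
  n1 <- replicate(250, ape::Ntip(
    simulate_piecewise_bd(bd_regime(0.2, 1 / 3), max_age = 12)$tree))
  ## same process through the two-state simulator with equal rates
  n2 <- replicate(250, ape::Ntip(
    simulate_bisse_tree(bisse_params(.3, .3, .1, .1, 0, 0),
                        max_age = 12)$tree))
  ks <- suppressWarnings(stats::ks.test(n1, n2))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted null shift is rarely detected", {
  set.seed(47)
  hits <- replicate(12, {
    s <- simulate_piecewise_bd(bd_regime(0.08, 0.3), max_age = 50,
                               shift_regime = bd_regime(0.08, 0.3),
                               shift_age = 10, min_shift_tips = 1)
    length(stepwise_search(s$tree, threshold = 10.5,
                           max_shifts = 2)$model$shift_edges)
  })
  expect_gte(mean(hits == 0), 0.9)
})

test_that("genus collapse conserves richness and is the identity at cap 1", {
  s <- simulate_bisse_tree(bisse_params(.3, .35, .05, .05, .04, .04),
                           max_age = 12, seed = 53)
  col1 <- collapse_simulated_genera(s$tree, s$tips, block_cap = 1)
  expect_equal(ape::Ntip(col1$tree), ape::Ntip(s$tree))
  expect_true(all(col1$tips$richness == 1))
  col <- collapse_simulated_genera(s$tree, s$tips, block_cap = 5)
  expect_equal(sum(col$tips$richness), ape::Ntip(s$tree))
  expect_true(all(col$richness$n0 + col$richness$n1 +
                    is.na(col$tips$state) * 0 >= 1))
  expect_lt(ape::Ntip(col$tree), ape::Ntip(s$tree))
  ## blocks are monophyletic by construction: each block's MRCA spans it
  for (b in col$blocks[lengths(col$blocks) > 1]) {
    m <- mrca_and_clade(s$tree, b)
    expect_setequal(m$subtree$tip.label, b)
  }
})

test_that("jittered tree sets preserve the root age and respect the scale", {
  set.seed(59)
  base <- as_timetree(ape::rcoal(40))
  same <- perturb_tree_set(base, 3, jitter = 0, seed = 1)
  for (tr in same)
    expect_identical(ape::write.tree(tr), ape::write.tree(base))
  set1 <- perturb_tree_set(base, 10, jitter = 0.02, seed = 2)
  set2 <- perturb_tree_set(base, 10, jitter = 0.12, seed = 2)
  expect_equal(vapply(set1, root_age, numeric(1)),
               rep(root_age(base), 10), tolerance = 1e-12)
  for (tr in c(set1, set2)) expect_silent(as_timetree(tr))
  ## node-age dispersion grows with the jitter scale
  age_sd <- function(set) {
    A <- vapply(set, node_ages, numeric(40 + base$Nnode))
    mean(apply(A[-(1:40), , drop = FALSE], 1, sd))
  }
  expect_gt(age_sd(set2), age_sd(set1))
})

test_that("the true parameters beat perturbed ones on small simulated trees", {
  set.seed(61)
  truth <- bisse_params(.3, .5, .1, .1, .06, .06)
  pert <- bisse_params(.75, 1.25, .1, .1, .06, .06)
  wins <- replicate(60, {
    s <- simulate_bisse_tree(truth, max_tips = 12)
    tree_loglik(s$tree, s$tips, truth) > tree_loglik(s$tree, s$tips, pert)
  })
  expect_gte(mean(wins), 0.7)
})
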