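test_that("branch integration matches the analytic decoupled solution", {
  p <- bisse_params(1, 0, 0, 0, 0, 0)
  s <- branch_integrate(tip_init(0, 1), p, 1)
  expect_equal(s$D[1] * exp(s$logfac), exp(-1), tolerance = 1e-8)
  expect_equal(s$E, c(0, 0))
  s0 <- branch_integrate(tip_init(1, 0.5), p, 0)
  expect_equal(s0, tip_init(1, 0.5))
})

test_that("branch integration agrees with a fixed-step RK4 oracle", {
  set.seed(31)
  for (i in 1:5) {
    p <- random_pars()
    y0 <- c(0.1, 0.2, 0.7, 0.4)
    res <- branch_integrate(list(E = y0[1:2], D = y0[3:4], logfac = 0), p, 2)
    oracle <- rk4_bisse(y0, unclass(p), 2, h = 1e-4)
    got <- c(res$E, res$D * exp(res$logfac))
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("tip initial conditions encode state and sampling fraction", {
  expect_equal(tip_init(0, 1), list(E = c(0, 0), D = c(1, 0), logfac = 0))
  s <- tip_init(1, 0.2966)
  expect_equal(s$D, c(0, 0.2966))
  expect_equal(s$E, c(0.7034, 0.7034))
  expect_equal(tip_init(NA, 1)$D, c(1, 1))
  expect_error(tip_init(0, 0), "in \\(0, 1\\]")
})

test_that("unresolved clade initial conditions reduce to their closed forms", {
  ## single known-state species with q = 0 equals a resolved tip
  p <- bisse_params(0.25, 0.4, 0.1, 0.15, 0, 0)
  u <- unresolved_clade_init(1, c(1, 0), duration = 5, pars = p, cap = 120)
  r <- branch_integrate(tip_init(0, 1), p, 5)
  expect_equal(u$D, r$D * exp(r$logfac), tolerance = 1e-6)
  expect_equal(u$E, r$E, tolerance = 1e-8)
  ## pure-birth geometric richness law
  py <- bisse_params(0.3, 0.3, 0, 0, 0, 0)
  for (n in c(1, 3, 5)) {
    u <- unresolved_clade_init(n, c(n, 0), duration = 6, pars = py, cap = 120)
    exact <- exp(-0.3 * 6) * (1 - exp(-0.3 * 6))^(n - 1)
    expect_equal(u$D[1], exact, tolerance = 1e-5)
  }
  ## degenerate duration
  u0 <- unresolved_clade_init(1, NULL, duration = 0, pars = py)
  expect_equal(u0$D, c(1, 1))
  expect_error(unresolved_clade_init(3, NULL, duration = 0, pars = py),
               "impossible")
  ## truncation guard
  expect_error(
    unresolved_clade_init(5, c(5, 0), duration = 8,
                          pars = bisse_params(.3, .3, 0, 0, 0, 0), cap = 40),
    "cap 40 exceeded")
})

test_that("cherry likelihood equals the analytic value", {
  p <- bisse_params(1, 0, 0, 0, 0, 0)
  td <- tip_data(c("A", "B"), c(0, 0), mode = "proportional", f = 1)
  ll <- tree_loglik(cherry(), td, p, root_mode = "given", root_state = 0)
  expect_equal(ll, -2, tolerance = 1e-8)
})

test_that("tree likelihood matches the RK4 post-order oracle on random trees", {
  set.seed(41)
  for (i in 1:4) {
    phy <- as_timetree(ape::rcoal(10))
    states <- setNames(sample(c(0, 1, NA), 10, replace = TRUE,
                              prob = c(.45, .45, .1)), phy$tip.label)
    p <- random_pars()
    f <- sample(c(1, 0.6), 1)
    td <- tip_data(phy$tip.label, states, mode = "proportional", f = f)
    ll <- tree_loglik(phy, td, p, root_mode = "weighted")
    oracle <- bisse_loglik_oracle(phy, states, unclass(p), f = f,
                                  root_mode = "weighted")
    expect_equal(ll, oracle, tolerance = 1e-6)
  }
})

test_that("relabeling states with swapped parameters leaves lnL unchanged", {
  set.seed(43)
  phy <- as_timetree(ape::rcoal(25))
  states <- sample(0:1, 25, replace = TRUE)
  td <- tip_data(phy$tip.label, states, mode = "proportional", f = 0.7)
  td_swapped <- tip_data(phy$tip.label, 1 - states, mode = "proportional",
                         f = 0.7)
  for (i in 1:3) {
    p <- random_pars()
    expect_equal(tree_loglik(phy, td, p),
                 tree_loglik(phy, td_swapped, swap_pars(p)),
                 tolerance = 1e-8)
  }
})

test_that("log-scale renormalization keeps extreme likelihoods finite", {
  set.seed(47)
  phy <- as_timetree(ape::rcoal(12))
  phy$edge.length <- phy$edge.length * (150 / root_age(phy))
  p <- bisse_params(1, 1.1, 0.9, 0.85, 0.02, 0.02)
  td <- tip_data(phy$tip.label, sample(0:1, 12, TRUE), mode = "proportional")
  ll <- tree_loglik(phy, td, p)
  expect_true(is.finite(ll))
  oracle <- bisse_loglik_oracle(phy, setNames(td$state, td$tip_label),
                                unclass(p), h = 5e-3)
  expect_equal(ll, oracle, tolerance = 1e-5)
})

test_that("equal-rate model with uninformative states is a constant-rate birth-death", {
  set.seed(53)
  phy <- as_timetree(ape::rcoal(15))
  phy$edge.length <- phy$edge.length * (10 / root_age(phy))
  td <- tip_data(phy$tip.label, NA, mode = "proportional", f = 1)
  lambda <- 0.35; mu <- 0.15
  p <- bisse_params(lambda, lambda, mu, mu, 0, 0)
  ll <- tree_loglik(phy, td, p, root_mode = "flat")
  ## D0 = D1, so the flat root mix equals the single-type likelihood
  expect_equal(ll, bd_loglik_closed(phy, lambda, mu), tolerance = 1e-6)
})

test_that("unresolved mode agrees with resolved mode in ranking parameters", {
  truth <- bisse_params(.2, .3, .02, .02, .05, .05)
  pert <- bisse_params(.35, .15, .02, .02, .05, .05)
  agree <- 0L; total <- 0L
  for (seed in c(2, 4, 6)) {
    sim <- simulate_bisse_tree(truth, max_age = 10, seed = seed)
    if (ape::Ntip(sim$tree) < 10) next
    col <- collapse_simulated_genera(sim$tree, sim$tips, block_cap = 4)
    ll_res <- tree_loglik(sim$tree, sim$tips, truth) -
      tree_loglik(sim$tree, sim$tips, pert)
    ll_un <- tree_loglik(col$tree, col$tips, truth, cap_extra = 300) -
      tree_loglik(col$tree, col$tips, pert, cap_extra = 300)
    total <- total + 1L
    agree <- agree + as.integer(sign(ll_res) == sign(ll_un))
  }
  expect_gte(total, 2L)
  expect_equal(agree, total)
})
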