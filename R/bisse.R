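## Binary-state speciation-extinction (BiSSE) likelihood.
##
## Parameters: lambda0/lambda1 (state-dependent speciation), mu0/mu1
## (extinction), q01 (0 -> 1, i.e. C3 -> C4 gain) and q10 (reversal), all in
## events / lineage / My.  The likelihood integrates, backward in time along
## every branch, the extinction probabilities E_i and subtree likelihood
## densities D_i, combines daughters at nodes with the speciation factor
## lambda_i, and applies a configurable root treatment.

#' BiSSE parameter vector
#'
#' @param lambda0,lambda1 state-dependent speciation rates (/My).
#' @param mu0,mu1 state-dependent extinction rates (/My).
#' @param q01 transition rate from state 0 to 1 (C3 -> C4).
#' @param q10 transition rate from state 1 to 0 (C4 -> C3).
#' @return a named numeric vector of class `bisse_params`; the derived net
#'   diversification rates `r0 = lambda0 - mu0`, `r1 = lambda1 - mu1` are
#'   available via [net_rates()].
#' @export
bisse_params <- function(lambda0, lambda1, mu0, mu1, q01, q10) {
  p <- c(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
         q01 = q01, q10 = q10)
  if (any(!is.finite(p)) || any(p < 0)) stop("all BiSSE rates must be >= 0")
  class(p) <- "bisse_params"
  p
}

#' Net diversification rates of a BiSSE parameter set
#' @param pars a [bisse_params()] vector.
#' @return named vector `c(r0, r1)` with `r_i = lambda_i - mu_i`.
#' @export
net_rates <- function(pars) {
  c(r0 = unname(pars["lambda0"] - pars["mu0"]),
    r1 = unname(pars["lambda1"] - pars["mu1"]))
}

as_pars6 <- function(pars) {
  p <- unclass(pars)[c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")]
  if (anyNA(p)) stop("invalid BiSSE parameter vector")
  unname(p)
}

#' Tip initial conditions under proportional sampling
#'
#' With a global sampling fraction `f`, a tip in state `i` starts with
#' `D_i = f`, `D_j = 0` (both equal to `f` when the state is unknown) and
#' `E_0 = E_1 = 1 - f`.
#'
#' @param state 0, 1 or `NA` (unknown).
#' @param f sampling fraction in (0, 1].
#' @return a BiSSE ODE state: list with `E`, `D` (length-2 vectors, order
#'   state 0 then 1) and `logfac` (accumulated log scaling, 0 here).
#' @export
tip_init <- function(state, f = 1) {
  if (!is.numeric(f) || f <= 0 || f > 1) stop("f must be in (0, 1]")
  D <- if (is.na(state)) c(f, f)
       else if (state == 0) c(f, 0)
       else if (state == 1) c(0, f)
       else stop("state must be 0, 1 or NA")
  list(E = c(1 - f, 1 - f), D = D, logfac = 0)
}

#' Integrate a BiSSE ODE state along a branch
#'
#' Propagates `(E, D)` backward in time over `duration` My at the given
#' rates.  `D` is renormalized if it underflows, with the scaling recorded
#' in `logfac`.
#'
#' @param state a BiSSE ODE state as returned by [tip_init()].
#' @param pars a [bisse_params()] vector.
#' @param duration branch length in My (>= 0).
#' @param rtol,atol relative and absolute ODE tolerances.
#' @return the integrated BiSSE ODE state.
#' @export
branch_integrate <- function(state, pars, duration, rtol = 1e-8,
                             atol = 1e-10) {
  if (duration < 0) stop("duration must be >= 0")
  res <- .bisse_branch_cpp(c(state$E, state$D), as_pars6(pars), duration,
                           rtol, atol)
  list(E = res$y[1:2], D = res$y[3:4], logfac = state$logfac + res$logfac)
}

## ---- terminally unresolved clades -----------------------------------------

# sparse generator (transposed) of the two-state linear birth-death-
# transition process on joint lineage counts (n0, n1), truncated at
# n0 + n1 <= cap with an absorbing overflow state
unresolved_generator <- function(pars, cap) {
  l0 <- pars[1]; l1 <- pars[2]; m0 <- pars[3]; m1 <- pars[4]
  q01 <- pars[5]; q10 <- pars[6]
  grid <- expand.grid(a = 0:cap, b = 0:cap)
  grid <- grid[grid$a + grid$b <= cap, ]
  a <- grid$a; b <- grid$b
  S <- nrow(grid)
  overflow <- S + 1L
  key <- function(x, y) x * (cap + 2L) + y
  keys <- key(a, b)
  id <- function(x, y) match(key(x, y), keys)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  addt <- function(src, dst, rate) {
    keep <- rate > 0
    ii <<- c(ii, dst[keep]); jj <<- c(jj, src[keep]); xx <<- c(xx, rate[keep])
  }
  src <- seq_len(S)
  at_cap <- (a + b) == cap
  tgt <- id(a + 1L, b); tgt[at_cap] <- overflow
  addt(src, tgt, a * l0)                       # birth in state 0
  tgt <- id(a, b + 1L); tgt[at_cap] <- overflow
  addt(src, tgt, b * l1)                       # birth in state 1
  addt(src, id(pmax(a - 1L, 0L), b), a * m0)   # death in state 0
  addt(src, id(a, pmax(b - 1L, 0L)), b * m1)   # death in state 1
  addt(src, id(pmax(a - 1L, 0L), b + 1L), a * q01)
  addt(src, id(a + 1L, pmax(b - 1L, 0L)), b * q10)
  tot <- a * (l0 + m0 + q01) + b * (l1 + m1 + q10)
  ii <- c(ii, src); jj <- c(jj, src); xx <- c(xx, -tot)
  list(QT = Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(overflow, overflow)),
       a = a, b = b, id = id, overflow = overflow)
}

#' Initial conditions for a terminally unresolved clade
#'
#' Computes `D_i`: the probability, under the two-state birth--death-
#' transition process started from a single lineage in state `i` at the
#' clade's stem attachment, of observing exactly the clade's species
#' richness (and per-state tallies, when known) at the present.  The joint
#' master equation over lineage counts `(n0, n1)` is integrated on a state
#' space truncated at `cap` total lineages; probability mass escaping the
#' truncation must stay below `mass_tol`.  `E_i` is computed by the usual
#' BiSSE extinction ODE with complete sampling (all of the clade's species
#' are accounted for by its richness).
#'
#' The returned state sits at the *stem* end of the clade's pendant branch,
#' so that branch must not be integrated again.
#'
#' @param richness total extant species in the clade (>= 1).
#' @param state_counts optional length-2 vector `c(n0, n1)` of per-state
#'   species counts summing to `richness`; omit when only the total is
#'   known.
#' @param duration time from the stem attachment to the present (My).
#' @param pars a [bisse_params()] vector.
#' @param cap truncation of total lineage count (default `richness + 200`).
#' @param mass_tol maximum tolerated probability mass beyond `cap`.
#' @param rtol,atol ODE tolerances.
#' @return a BiSSE ODE state (list `E`, `D`, `logfac`).
#' @export
unresolved_clade_init <- function(richness, state_counts = NULL, duration,
                                  pars, cap = richness + 200L,
                                  mass_tol = 1e-7, rtol = 1e-8,
                                  atol = 1e-12) {
  if (richness < 1) stop("richness must be >= 1")
  if (cap < richness) stop("cap must be >= richness")
  if (!is.null(state_counts)) {
    if (length(state_counts) != 2L || sum(state_counts) != richness)
      stop("state_counts must be length 2 and sum to richness")
  }
  p6 <- as_pars6(pars)
  if (duration == 0) {
    D <- if (is.null(state_counts)) {
      if (richness == 1L) c(1, 1) else c(0, 0)
    } else c(as.numeric(all(state_counts == c(1, 0))),
             as.numeric(all(state_counts == c(0, 1))))
    if (all(D == 0)) stop("richness > 1 impossible at duration 0")
    return(list(E = c(0, 0), D = D, logfac = 0))
  }
  ## E by the standard extinction ODE, f = 1
  E <- branch_integrate(list(E = c(0, 0), D = c(1, 1), logfac = 0),
                        pars, duration, rtol = rtol, atol = atol)$E
  gen <- unresolved_generator(p6, cap)
  rhs <- function(t, y, parms) list(as.vector(gen$QT %*% y))
  targets <- if (is.null(state_counts)) {
    which(gen$a + gen$b == richness)
  } else gen$id(state_counts[1], state_counts[2])
  D <- numeric(2)
  for (i in 1:2) {
    y0 <- numeric(gen$overflow)
    y0[if (i == 1) gen$id(1L, 0L) else gen$id(0L, 1L)] <- 1
    sol <- deSolve::ode(y = y0, times = c(0, duration), func = rhs,
                        parms = NULL, method = "adams", rtol = rtol,
                        atol = atol)
    pfin <- sol[nrow(sol), -1]
    if (pfin[gen$overflow] > mass_tol)
      stop(sprintf(paste0("unresolved-clade truncation cap %d exceeded: ",
                          "escaped mass %.3g > mass_tol %.3g"),
                   cap, pfin[gen$overflow], mass_tol))
    D[i] <- sum(pfin[targets])
  }
  list(E = E, D = pmax(D, 0), logfac = 0)
}

# batched unresolved-clade initial conditions: one master-equation
# integration per start state, outputs read at each clade's stem age.
# Returns a matrix with columns (E0, E1, D0, D1), rows in input order.
unresolved_batch <- function(richness, state, durations, pars, cap,
                             mass_tol = 1e-7, rtol = 1e-8, atol = 1e-12) {
  p6 <- as_pars6(pars)
  gen <- unresolved_generator(p6, cap)
  rhs <- function(t, y, parms) list(as.vector(gen$QT %*% y))
  times <- sort(unique(c(0, durations)))
  out <- matrix(0, length(richness), 4)
  D <- array(0, c(length(richness), 2))
  for (i in 1:2) {
    y0 <- numeric(gen$overflow)
    y0[if (i == 1) gen$id(1L, 0L) else gen$id(0L, 1L)] <- 1
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "adams", rtol = rtol, atol = atol)
    for (k in seq_along(richness)) {
      pfin <- sol[match(durations[k], times), -1]
      if (pfin[gen$overflow] > mass_tol)
        stop(sprintf(paste0("unresolved-clade truncation cap %d exceeded ",
                            "at stem age %.3g: escaped mass %.3g > %.3g"),
                     cap, durations[k], pfin[gen$overflow], mass_tol))
      targets <- if (is.na(state[k])) which(gen$a + gen$b == richness[k])
                 else if (state[k] == 0) gen$id(richness[k], 0L)
                 else gen$id(0L, richness[k])
      D[k, i] <- max(sum(pfin[targets]), 0)
    }
  }
  for (k in seq_along(richness)) {
    E <- branch_integrate(list(E = c(0, 0), D = c(1, 1), logfac = 0),
                          pars, durations[k], rtol = rtol, atol = atol)$E
    out[k, ] <- c(E, D[k, ])
  }
  out
}

## ---- whole-tree likelihood -------------------------------------------------

root_weights <- function(D, pars, root_mode, root_state) {
  switch(root_mode,
    weighted = if (sum(D) > 0) D / sum(D) else c(0.5, 0.5),
    flat = c(0.5, 0.5),
    equilibrium = {
      qs <- pars["q01"] + pars["q10"]
      if (qs > 0) c(pars["q10"], pars["q01"]) / qs else c(0.5, 0.5)
    },
    given = {
      if (is.null(root_state) || !(root_state %in% 0:1))
        stop("root_mode = 'given' requires root_state 0 or 1")
      if (root_state == 0) c(1, 0) else c(0, 1)
    },
    stop("unknown root mode"))
}

#' BiSSE log-likelihood of a tree and tip data
#'
#' Post-order pruning likelihood for the binary-state speciation--extinction
#' model.  Missing diversity is handled according to the sampling mode of
#' `tips`: `"proportional"` tips enter with the global sampling fraction
#' `f`; `"unresolved"` tips with richness > 1 are treated as terminally
#' unresolved clades via [unresolved_clade_init()].  At the root, the two
#' state-conditional likelihoods are combined according to `root_mode`:
#' `"weighted"` (each state weighted by its relative likelihood, the
#' default), `"flat"`, `"equilibrium"` (transition-rate equilibrium
#' frequencies) or `"given"` (condition on `root_state`).  Optional
#' conditioning on survival divides each `D_i` by `lambda_i (1 - E_i)^2`.
#'
#' @param phy an ultrametric, bifurcating `phylo` object (polytomies are
#'   resolved with zero-length branches by [as_timetree()]).
#' @param tips a [tip_data()] table covering every tip.
#' @param pars a [bisse_params()] vector.
#' @param root_mode one of `"weighted"`, `"flat"`, `"equilibrium"`,
#'   `"given"`.
#' @param root_state root state (0/1) when `root_mode = "given"`.
#' @param condition_on_survival logical; default `FALSE`.
#' @param rtol,atol ODE tolerances.
#' @param cap_extra truncation headroom for unresolved clades (cap =
#'   richness + `cap_extra`).
#' @param mass_tol tolerated escaped probability mass for unresolved clades.
#' @return the log-likelihood (a single finite number).
#' @export
tree_loglik <- function(phy, tips, pars,
                        root_mode = c("weighted", "flat", "equilibrium",
                                      "given"),
                        root_state = NULL, condition_on_survival = FALSE,
                        rtol = 1e-8, atol = 1e-10, cap_extra = 200L,
                        mass_tol = 1e-7) {
  root_mode <- match.arg(root_mode)
  phy <- as_timetree(phy)
  tips <- match_tips(tips, phy)
  mode <- attr(tips, "mode"); f <- attr(tips, "f")
  ntip <- ape::Ntip(phy)
  init <- matrix(0, ntip, 4)
  logfac <- numeric(ntip)
  skip <- logical(ntip)
  if (mode == "proportional") {
    if (any(tips$richness != 1L))
      stop("proportional mode expects every tip to have richness 1; ",
           "use the 'unresolved' mode for richness > 1 tips")
    for (i in seq_len(ntip)) {
      s <- tip_init(tips$state[i], f)
      init[i, ] <- c(s$E, s$D)
    }
  } else {
    if (f != 1) stop("unresolved mode implies complete assigned sampling (f = 1)")
    age <- node_ages(phy)
    parent <- phy$edge[match(seq_len(ntip), phy$edge[, 2]), 1]
    unres <- which(tips$richness > 1L)
    for (i in setdiff(seq_len(ntip), unres)) {
      s <- tip_init(tips$state[i], 1)
      init[i, ] <- c(s$E, s$D)
    }
    if (length(unres)) {
      ## all unresolved clades share the same master equation started from
      ## one lineage, so integrate once per start state and read each
      ## clade's count distribution at its own stem age
      init[unres, ] <- unresolved_batch(tips$richness[unres],
                                        tips$state[unres], age[parent[unres]],
                                        pars, max(tips$richness) + cap_extra,
                                        mass_tol, rtol)
      skip[unres] <- TRUE
    }
  }
  po <- ape::reorder.phylo(phy, "postorder")
  res <- .bisse_postorder_cpp(ntip, phy$Nnode, po$edge, po$edge.length,
                              init, logfac, skip, as_pars6(pars), rtol, atol)
  D <- res$D; E <- res$E
  if (condition_on_survival) {
    denom <- as_pars6(pars)[1:2] * (1 - E)^2
    if (any(denom <= 0)) stop("survival conditioning undefined (E = 1)")
    D <- D / denom
  }
  w <- root_weights(D, pars, root_mode, root_state)
  val <- sum(w * D)
  if (!is.finite(val) || val <= 0)
    stop("zero root likelihood: numerical failure or impossible data")
  log(val) + res$logfac
}
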