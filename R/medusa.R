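## Piecewise constant-rate birth-death fitting with terminally unresolved
## richness, and greedy AICc-driven detection of diversification-rate
## shifts (MEDUSA-style).
##
## A regime is parameterized by its net diversification rate r = lambda - mu
## (/My) and relative extinction eps = mu / lambda in [0, 1).  The workhorse
## closed forms for a lineage of age t are
##   beta(t) = (e^{rt} - 1) / (e^{rt} - eps)        (geometric parameter)
##   E(t)    = eps * beta(t)                        (extinction probability)
## so that P(n extant species | t, survival) = (1 - beta) beta^{n-1}, and
## the reconstructed-process density of a resolved branch follows from the
## per-lineage factor Psi(t) = (1 - E(t)) (1 - beta(t)).

#' Birth-death regime
#'
#' @param r net diversification rate `lambda - mu` (/My, > 0).
#' @param eps relative extinction `mu / lambda` in `[0, 1)`.
#' @return list with `r`, `eps` and the derived `lambda = r / (1 - eps)`,
#'   `mu = lambda * eps`.
#' @export
bd_regime <- function(r, eps = 0) {
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  if (r <= 0) stop("net diversification rate must be > 0")
  lambda <- r / (1 - eps)
  list(r = r, eps = eps, lambda = lambda, mu = lambda * eps)
}

# beta(t); the r -> 0 limit lambda*t / (1 + lambda*t) is reached through
# expm1, which stays accurate for small r*t
bd_beta <- function(r, eps, t) {
  g <- expm1(r * t)
  g / (g + 1 - eps)
}

bd_E <- function(r, eps, t) eps * bd_beta(r, eps, t)

#' Log-probability of a clade's species richness under a birth-death regime
#'
#' Probability of `n` extant species descending from one lineage after time
#' `t`, conditioned on survival: the geometric law
#' `P(n | t, survival) = (1 - beta) beta^{n-1}`.
#'
#' @param n species richness (>= 1); vectorized.
#' @param t stem age in My; vectorized.
#' @param regime a [bd_regime()].
#' @return log-probability term(s).
#' @export
richness_loglik <- function(n, t, regime) {
  b <- bd_beta(regime$r, regime$eps, t)
  log1p(-b) + (n - 1) * log(b)
}

# log Psi(t): per-lineage reconstructed-process factor
bd_lnpsi <- function(r, eps, t) {
  b <- bd_beta(r, eps, t)
  log1p(-eps * b) + log1p(-b)
}

# log-likelihood of one regime given its sufficient data:
#   n_events * log(lambda)
# + sum over resolved internal branches of lnPsi(t_old) - lnPsi(t_young)
# + sum over richness data of the unconditional clade-size probability
#   P(n | t) = Psi(t) beta^{n-1}, which at n = 1 is exactly the pendant
#   branch factor, so the model reduces to a resolved-tree birth-death fit
#   when every tip has richness 1
# - survival conditioning for the regime's basal lineage(s) when requested
regime_loglik <- function(r, eps, t_old, t_young, n_events, rich_n, rich_t,
                          base_t, condition = TRUE) {
  lambda <- r / (1 - eps)
  ll <- n_events * log(lambda)
  if (length(t_old))
    ll <- ll + sum(bd_lnpsi(r, eps, t_old) - bd_lnpsi(r, eps, t_young))
  if (length(rich_n)) {
    b <- bd_beta(r, eps, rich_t)
    ll <- ll + sum(log1p(-eps * b) + log1p(-b) + (rich_n - 1) * log(b))
  }
  if (condition && length(base_t))
    ll <- ll - sum(log1p(-bd_E(r, eps, base_t)))
  ll
}

# maximize regime_loglik over (log r, logit eps); deterministic multi-start
fit_regime <- function(t_old, t_young, n_events, rich_n, rich_t, base_t,
                       condition = TRUE, eps_max = 0.999,
                       start_par = NULL, reltol = 1e-10) {
  tot_len <- sum(t_old - t_young) + sum(rich_t)
  r0 <- max((n_events + sum(pmax(rich_n - 1, 0)) + 1) / max(tot_len, 1e-8),
            1e-6)
  obj <- function(p) {
    r <- exp(p[1])
    eps <- eps_max * stats::plogis(p[2])
    val <- regime_loglik(r, eps, t_old, t_young, n_events, rich_n, rich_t,
                         base_t, condition)
    if (!is.finite(val)) 1e10 else -val
  }
  starts <- if (is.null(start_par)) {
    list(c(log(r0), stats::qlogis(0.05)),
         c(log(r0), stats::qlogis(0.5)),
         c(log(r0 * 0.3), stats::qlogis(0.9)))
  } else list(start_par)
  best <- NULL
  for (p0 in starts) {
    opt <- tryCatch(optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 1000L, reltol = reltol)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("regime optimization failed")
  list(r = exp(best$par[1]), eps = eps_max * stats::plogis(best$par[2]),
       lnL = -best$value, par = best$par)
}

#' Reconstructed-process birth-death log-likelihood of a resolved tree
#'
#' Log-density of the observed internal node ages of `phy` under a single
#' constant-rate regime: one `log(lambda)` per non-root internal node,
#' per-branch reconstructed-process factors over internal branches, the
#' unconditional clade-size probability `Psi(t) beta^(n-1)` for every
#' pendant branch (which at richness 1 is exactly the pendant branch
#' factor of the resolved-tree likelihood), and optional conditioning on
#' survival of the two root lineages.
#'
#' @param phy an ultrametric `phylo` object.
#' @param regime a [bd_regime()].
#' @param condition condition on survival of the root's two daughter
#'   lineages (default `TRUE`).
#' @param richness optional data.frame with columns `tip_label`,
#'   `richness` for terminally unresolved tips (default: all 1).
#' @return the log-likelihood.
#' @export
backbone_loglik <- function(phy, regime, condition = TRUE, richness = NULL) {
  md <- medusa_data(phy, richness)
  regime_loglik(regime$r, regime$eps,
                md$t_old[md$internal], md$t_young[md$internal],
                n_events = sum(md$internal),
                rich_n = md$rich_n[!md$internal],
                rich_t = md$t_old[!md$internal],
                base_t = rep(root_age(phy), 2), condition = condition)
}

# per-edge tables used by the shift machinery
medusa_data <- function(phy, richness = NULL) {
  phy <- ape::reorder.phylo(as_timetree(phy), "cladewise")
  ntip <- ape::Ntip(phy)
  age <- node_ages(phy)
  ne <- nrow(phy$edge)
  t_old <- age[phy$edge[, 1]]
  t_young <- age[phy$edge[, 2]]
  internal <- phy$edge[, 2] > ntip
  rich_n <- rep(NA_real_, ne)
  rich <- setNames(rep(1, ntip), phy$tip.label)
  if (!is.null(richness)) {
    i <- match(richness$tip_label, phy$tip.label)
    if (anyNA(i)) stop("richness table names tips absent from the tree")
    rich[i] <- richness$richness
  }
  rich_n[!internal] <- rich[phy$edge[!internal, 2]]
  ## edges of the stem-inclusive subtree below each edge (self included)
  po <- ape::reorder.phylo(phy, "postorder")
  ord <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  desc <- vector("list", ne)
  kids <- split(seq_len(ne), phy$edge[, 1])
  for (k in ord) {
    ch <- phy$edge[k, 2]
    below <- if (ch > ntip) unlist(desc[kids[[as.character(ch)]]]) else integer(0)
    desc[[k]] <- c(k, below)
  }
  list(phy = phy, ntip = ntip, ne = ne, t_old = t_old, t_young = t_young,
       internal = internal, rich_n = rich_n, desc = desc,
       parent_edge = match(phy$edge[, 1], phy$edge[, 2]),
       root_age = root_age(phy))
}

# nearest-rootward-shift regime assignment; shift_edges ordered, regime
# ids 2, 3, ...; regime 1 at the root
assign_regimes <- function(md, shift_edges) {
  regime <- integer(md$ne)
  ## cladewise edge order visits every edge after its parent edge
  for (k in seq_len(md$ne)) {
    s <- match(k, shift_edges)
    if (!is.na(s)) regime[k] <- s + 1L
    else {
      pe <- md$parent_edge[k]
      regime[k] <- if (is.na(pe)) 1L else regime[pe]
    }
  }
  regime
}

regime_fit_for <- function(md, edges, base_t, condition, ...) {
  int <- edges[md$internal[edges]]
  pen <- edges[!md$internal[edges]]
  fit_regime(md$t_old[int], md$t_young[int], n_events = length(int),
             rich_n = md$rich_n[pen], rich_t = md$t_old[pen],
             base_t = base_t, condition = condition, ...)
}

shift_model_from <- function(md, shift_edges, regime, fits, condition,
                             threshold = NA_real_) {
  R <- length(shift_edges) + 1L
  lnL <- sum(vapply(fits, `[[`, numeric(1), "lnL"))
  k <- 2L * R + (R - 1L)
  n_obs <- md$phy$Nnode + sum(!md$internal)
  aicc <- -2 * lnL + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
  regimes <- data.frame(
    regime = seq_len(R),
    shift_edge = c(NA_integer_, shift_edges),
    stem_age = c(md$root_age, md$t_old[shift_edges]),
    crown_age = c(md$root_age, md$t_young[shift_edges]),
    clade = c("root", vapply(shift_edges, function(e) {
      ch <- md$phy$edge[e, 2]
      if (ch <= md$ntip) md$phy$tip.label[ch]
      else paste0("mrca(", paste(head(ape::extract.clade(md$phy, ch)$tip.label,
                                      2), collapse = ","), ")")
    }, character(1))),
    r = vapply(fits, `[[`, numeric(1), "r"),
    eps = vapply(fits, `[[`, numeric(1), "eps"),
    n_edges = as.vector(table(factor(regime, levels = seq_len(R)))),
    lnL = vapply(fits, `[[`, numeric(1), "lnL"))
  regimes$lambda <- regimes$r / (1 - regimes$eps)
  regimes$mu <- regimes$lambda * regimes$eps
  out <- list(regimes = regimes, shift_edges = shift_edges,
              assignment = regime, lnL = lnL, k = k, n_obs = n_obs,
              AICc = aicc, condition = condition, threshold = threshold)
  class(out) <- "shift_model"
  out
}

#' Fit a piecewise birth-death model with fixed shift locations
#'
#' Each shift branch starts a new regime governing that branch and its
#' entire subtree (stem-inclusive), except where a more tipward shift takes
#' over; regime 1 holds the root.  Per-regime `(r, eps)` are maximized
#' independently; the total log-likelihood is the sum of backbone and
#' richness terms and AICc uses `k = 2 * regimes + (regimes - 1)` and
#' `n_obs` = internal nodes + richness data.
#'
#' @param phy an ultrametric `phylo` object (genus-level tree).
#' @param richness optional data.frame `tip_label`, `richness` (default all
#'   1, i.e. sampled tips only).
#' @param shifts integer vector of shift edge indices (rows of `phy$edge`),
#'   distinct.
#' @param condition condition each regime on survival of its basal
#'   lineage(s) (default `TRUE`).
#' @return a `shift_model`: regimes table (stem/crown age, r, eps, lambda,
#'   mu, per-regime lnL), total `lnL`, `k`, `n_obs`, `AICc`, and the
#'   per-edge regime `assignment`.
#' @export
fit_shift_model <- function(phy, richness = NULL, shifts = integer(0),
                            condition = TRUE) {
  md <- medusa_data(phy, richness)
  shifts <- as.integer(shifts)
  if (anyDuplicated(shifts)) stop("shift branches must be distinct")
  if (any(shifts < 1L | shifts > md$ne)) stop("shift edge index out of range")
  regime <- assign_regimes(md, shifts)
  fits <- lapply(seq_len(length(shifts) + 1L), function(j) {
    edges <- which(regime == j)
    if (!length(edges)) stop("regime ", j, " has no data")
    base_t <- if (j == 1L) rep(md$root_age, 2) else md$t_old[shifts[j - 1L]]
    regime_fit_for(md, edges, base_t, condition)
  })
  shift_model_from(md, shifts, regime, fits, condition)
}

#' @method print shift_model
#' @export
print.shift_model <- function(x, ...) {
  cat("Piecewise birth-death model:", nrow(x$regimes), "regime(s), lnL =",
      format(x$lnL, digits = 8), ", AICc =", format(x$AICc, digits = 8),
      "\n")
  print(x$regimes[, c("regime", "clade", "stem_age", "crown_age", "r",
                      "eps", "lnL")], row.names = FALSE, digits = 5)
  invisible(x)
}

#' Greedy stepwise search for diversification-rate shifts
#'
#' Starting from a single-regime fit, repeatedly evaluates adding one shift
#' on every eligible branch, accepting the best candidate if it improves
#' AICc by at least `threshold`; stops otherwise or at `max_shifts`.  Ties
#' in AICc improvement are broken by older stem age, then edge order.  The
#' usual thresholds are the turboMEDUSA genus-tree default 8.4547, the
#' conservative 10.5, and 17 for very large trees; the threshold is always
#' explicit here.
#'
#' @inheritParams fit_shift_model
#' @param threshold required AICc improvement per accepted shift (> 0;
#'   `Inf` accepts nothing).
#' @param max_shifts maximum number of shifts to add.
#' @return a `medusa_search`: list with `model` (final accepted
#'   `shift_model`), `steps` (per-step table of best candidate and AICc),
#'   and the accepted `models` sequence (base model first).
#' @export
stepwise_search <- function(phy, richness = NULL, threshold = 8.4547,
                            max_shifts = 20L, condition = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  md <- medusa_data(phy, richness)
  shifts <- integer(0)
  regime <- assign_regimes(md, shifts)
  fits <- list(regime_fit_for(md, which(regime == 1L),
                              rep(md$root_age, 2), condition))
  current <- shift_model_from(md, shifts, regime, fits, condition, threshold)
  models <- list(current)
  steps <- data.frame(step = 0L, shift_edge = NA_integer_,
                      lnL = current$lnL, AICc = current$AICc,
                      improvement = NA_real_, accepted = TRUE)
  while (length(shifts) < max_shifts) {
    cand <- setdiff(seq_len(md$ne), shifts)
    best <- NULL
    for (e in cand) {
      j <- regime[e]                 # regime being split
      sub <- md$desc[[e]]
      sub <- sub[regime[sub] == j]   # stem-inclusive, nearest-shift rule
      rest <- setdiff(which(regime == j), sub)
      if (!length(rest)) next        # splitting away the whole regime
      base_t <- if (j == 1L) rep(md$root_age, 2)
                else md$t_old[shifts[j - 1L]]
      ## screening pass: single start from the split regime's current
      ## optimum, moderate tolerance; the chosen candidate is refit below
      sp <- fits[[j]]$par
      f_new <- tryCatch(regime_fit_for(md, sub, md$t_old[e], condition,
                                       start_par = sp, reltol = 1e-8),
                        error = function(err) NULL)
      f_rest <- tryCatch(regime_fit_for(md, rest, base_t, condition,
                                        start_par = sp, reltol = 1e-8),
                         error = function(err) NULL)
      if (is.null(f_new) || is.null(f_rest)) next
      others <- sum(vapply(fits[-j], `[[`, numeric(1), "lnL"))
      lnL <- others + f_new$lnL + f_rest$lnL
      R <- length(shifts) + 2L
      k <- 2L * R + (R - 1L)
      n_obs <- current$n_obs
      aicc <- -2 * lnL + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
      better <- is.null(best) || aicc < best$aicc - 1e-9 ||
        (abs(aicc - best$aicc) <= 1e-9 && md$t_old[e] > md$t_old[best$e])
      if (better)
        best <- list(e = e, aicc = aicc, lnL = lnL, f_new = f_new,
                     f_rest = f_rest, j = j)
    }
    if (is.null(best)) break
    ## precise refit of the winning split (full multi-start)
    base_t_best <- if (best$j == 1L) rep(md$root_age, 2)
                   else md$t_old[shifts[best$j - 1L]]
    sub <- md$desc[[best$e]]
    sub <- sub[regime[sub] == best$j]
    rest <- setdiff(which(regime == best$j), sub)
    best$f_new <- regime_fit_for(md, sub, md$t_old[best$e], condition)
    best$f_rest <- regime_fit_for(md, rest, base_t_best, condition)
    others <- sum(vapply(fits[-best$j], `[[`, numeric(1), "lnL"))
    best$lnL <- others + best$f_new$lnL + best$f_rest$lnL
    R <- length(shifts) + 2L
    k <- 2L * R + (R - 1L)
    best$aicc <- -2 * best$lnL + 2 * k +
      2 * k * (k + 1) / (current$n_obs - k - 1)
    improvement <- current$AICc - best$aicc
    accepted <- improvement >= threshold
    steps <- rbind(steps, data.frame(
      step = length(shifts) + 1L, shift_edge = best$e, lnL = best$lnL,
      AICc = best$aicc, improvement = improvement, accepted = accepted))
    if (!accepted) break
    shifts <- c(shifts, best$e)
    fits[[best$j]] <- best$f_rest
    fits[[length(shifts) + 1L]] <- best$f_new
    regime <- assign_regimes(md, shifts)
    ## regimes other than the split one keep their fit; refresh bookkeeping
    current <- shift_model_from(md, shifts, regime, fits, condition,
                                threshold)
    models[[length(models) + 1L]] <- current
  }
  out <- list(model = current, models = models, steps = steps,
              threshold = threshold)
  class(out) <- "medusa_search"
  out
}

#' @method print medusa_search
#' @export
print.medusa_search <- function(x, ...) {
  cat("Stepwise shift search (threshold", x$threshold, "AICc units):",
      length(x$model$shift_edges), "shift(s) accepted\n")
  print(x$steps, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Shift table in publication form
#'
#' One row per regime: shift id, clade label, stem and crown ages of the
#' shift branch, `r`, `eps`, and the AICc of the model at the step where
#' the shift was accepted.
#'
#' @param x a `medusa_search` or `shift_model` object.
#' @return a data.frame.
#' @export
shift_table <- function(x) {
  m <- if (inherits(x, "medusa_search")) x$model else x
  tab <- m$regimes[, c("regime", "clade", "stem_age", "crown_age", "r",
                       "eps", "lambda", "mu")]
  if (inherits(x, "medusa_search")) {
    acc <- x$steps[x$steps$accepted, ]
    tab$AICc_at_step <- acc$AICc[match(c(0L, seq_along(m$shift_edges)),
                                       acc$step)]
  }
  tab
}
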