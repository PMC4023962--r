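## Constrained BiSSE model family, maximum-likelihood fitting and model
## comparison.  The family mirrors the usual four-model design for a binary
## trait: equal diversification (lambda and mu both shared, 4 free
## parameters), equal speciation (5), equal extinction (5) and the full
## model (6).

#' Constrained BiSSE model specification
#'
#' @param model one of `"equal_div"` (`lambda0 = lambda1`, `mu0 = mu1`),
#'   `"equal_spec"` (`lambda0 = lambda1`), `"equal_ext"` (`mu0 = mu1`) or
#'   `"full"`.
#' @return a list with the free-parameter names, `k` (number of free
#'   parameters), and functions `expand` (free vector -> full 6-rate
#'   vector) and `collapse` (6-rate vector -> free vector).
#' @export
model_spec <- function(model = c("full", "equal_div", "equal_spec",
                                 "equal_ext")) {
  model <- match.arg(model)
  defs <- list(
    equal_div = list(free = c("lambda", "mu", "q01", "q10"),
                     map = c(lambda0 = "lambda", lambda1 = "lambda",
                             mu0 = "mu", mu1 = "mu",
                             q01 = "q01", q10 = "q10"),
                     merged = c(lambda = TRUE, mu = TRUE)),
    equal_spec = list(free = c("lambda", "mu0", "mu1", "q01", "q10"),
                      map = c(lambda0 = "lambda", lambda1 = "lambda",
                              mu0 = "mu0", mu1 = "mu1",
                              q01 = "q01", q10 = "q10"),
                      merged = c(lambda = TRUE, mu = FALSE)),
    equal_ext = list(free = c("lambda0", "lambda1", "mu", "q01", "q10"),
                     map = c(lambda0 = "lambda0", lambda1 = "lambda1",
                             mu0 = "mu", mu1 = "mu",
                             q01 = "q01", q10 = "q10"),
                     merged = c(lambda = FALSE, mu = TRUE)),
    full = list(free = c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10"),
                map = c(lambda0 = "lambda0", lambda1 = "lambda1",
                        mu0 = "mu0", mu1 = "mu1",
                        q01 = "q01", q10 = "q10"),
                merged = c(lambda = FALSE, mu = FALSE)))
  d <- defs[[model]]
  full_names <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  expand <- function(theta) {
    p <- setNames(theta[d$map], full_names)
    do.call(bisse_params, as.list(p))
  }
  collapse <- function(p6) {
    v <- unclass(p6)
    out <- numeric(length(d$free))
    names(out) <- d$free
    for (nm in d$free) {
      src <- names(d$map)[d$map == nm]
      out[nm] <- mean(v[src])
    }
    out
  }
  list(name = model, free = d$free, k = length(d$free), merged = d$merged,
       expand = expand, collapse = collapse)
}

# is model a nested within model b?  (a's equality constraints are a
# superset of b's)
is_nested <- function(a, b) {
  all(a$merged >= b$merged) && a$k <= b$k
}

# crude moment starting values: a Yule-flavoured net-rate estimate, 50%
# relative extinction, and a parsimony-style transition rate
moment_start <- function(phy, tips) {
  ntip <- ape::Ntip(phy)
  ra <- root_age(phy)
  f <- attr(tips, "f")
  n_eff <- sum(tips$richness) / max(f, 1e-3)
  r <- max((log(n_eff) - log(2)) / ra, 1e-3)
  st <- tips$state
  changes <- if (all(is.na(st)) || length(unique(na.omit(st))) < 2L) 0L
             else fitch_changes(phy, st)
  q <- max(changes, 1) / sum(phy$edge.length)
  c(lambda0 = 2 * r, lambda1 = 2 * r, mu0 = r, mu1 = r, q01 = q, q10 = q)
}

# Fitch parsimony count of binary-state changes (NA tips uninformative)
fitch_changes <- function(phy, states) {
  ntip <- ape::Ntip(phy)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip))
    sets[[i]] <- if (is.na(states[i])) 0:1 else states[i]
  po <- ape::reorder.phylo(phy, "postorder")
  changes <- 0L
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (is.null(sets[[p]])) sets[[p]] <- sets[[ch]]
    else {
      inter <- intersect(sets[[p]], sets[[ch]])
      if (length(inter)) sets[[p]] <- inter
      else { sets[[p]] <- union(sets[[p]], sets[[ch]]); changes <- changes + 1L }
    }
  }
  changes
}

# deterministic multiplicative perturbations applied to the moment start
start_multipliers <- function(n_starts) {
  M <- rbind(c(1,   1,   1,   1,   1,   1),
             c(2,   2,   0.5, 0.5, 1,   1),
             c(0.5, 0.5, 1.5, 1.5, 1,   1),
             c(1,   2,   1,   0.5, 2,   0.5),
             c(2,   0.5, 0.5, 1,   0.5, 2))
  colnames(M) <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  M[rep_len(seq_len(nrow(M)), n_starts), , drop = FALSE]
}

#' Maximum-likelihood BiSSE fit under a constrained model
#'
#' Maximizes [tree_loglik()] over the free parameters of `model` on the log
#' scale with bounded quasi-Newton (`L-BFGS-B`), from `n_starts`
#' deterministic starting points (fixed multiplicative perturbations of a
#' birth--death moment estimate).  The best converged start is returned.
#'
#' @inheritParams tree_loglik
#' @param model model name, see [model_spec()].
#' @param n_starts number of deterministic starting points (default 5).
#' @param lower,upper bounds for every rate (/My).
#' @param control passed to [stats::optim()].
#' @param ... passed to [tree_loglik()] (root mode, conditioning,
#'   tolerances).
#' @return a `bisse_fit` object: list with `model`, `k`, `pars` (the 6 MLE
#'   rates), `net_rates`, `lnL`, `converged`, `starts` (per-start summary)
#'   and the fit configuration.
#' @export
fit_model <- function(phy, tips, model = "full", n_starts = 5L,
                      lower = 1e-8, upper = 1e3, control = list(), ...) {
  spec <- if (is.list(model)) model else model_spec(model)
  phy <- as_timetree(phy)
  tips <- match_tips(tips, phy)
  base <- moment_start(phy, tips)
  mults <- start_multipliers(n_starts)
  nll <- function(theta_log) {
    th <- exp(theta_log)
    names(th) <- spec$free
    val <- tryCatch(
      -tree_loglik(phy, tips, spec$expand(th), ...),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  ctrl <- modifyList(list(maxit = 500L), control)
  best <- NULL
  starts <- data.frame(start = seq_len(n_starts), lnL = NA_real_,
                       convergence = NA_integer_)
  for (s in seq_len(n_starts)) {
    p0 <- spec$collapse(pmin(pmax(base * mults[s, ], lower), upper))
    opt <- tryCatch(
      optim(log(p0), nll, method = "L-BFGS-B", lower = log(lower),
            upper = log(upper), control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    starts$lnL[s] <- -opt$value
    starts$convergence[s] <- opt$convergence
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10)
    stop("no starting point converged to a finite likelihood")
  th <- exp(best$par)
  names(th) <- spec$free
  pars <- spec$expand(th)
  out <- list(model = spec$name, k = spec$k, pars = pars,
              net_rates = net_rates(pars), lnL = -best$value,
              converged = best$convergence == 0, starts = starts,
              n_tip = ape::Ntip(phy), mode = attr(tips, "mode"),
              f = attr(tips, "f"), spec = spec,
              config = list(...))
  class(out) <- "bisse_fit"
  out
}

#' @method print bisse_fit
#' @export
print.bisse_fit <- function(x, ...) {
  cat("BiSSE fit (", x$model, " model, k = ", x$k, ")\n", sep = "")
  cat("  lnL = ", format(x$lnL, digits = 8), if (!x$converged) " (NOT converged)",
      "\n", sep = "")
  print(round(unclass(x$pars), 5))
  cat("  net rates: r0 = ", round(x$net_rates["r0"], 5),
      ", r1 = ", round(x$net_rates["r1"], 5), "\n", sep = "")
  invisible(x)
}

#' Compare fitted BiSSE models by likelihood ratio and information criteria
#'
#' For every nested pair among the supplied fits (fitted on the same data),
#' reports the likelihood-ratio statistic `2 * (lnL_general -
#' lnL_constrained)`, its degrees of freedom and chi-squared p-value, along
#' with AIC and AICc for each model.  The lowest-AICc model is flagged as
#' preferred.
#'
#' @param fits a list of `bisse_fit` objects (or several passed via `...`).
#' @param ... further `bisse_fit` objects.
#' @return a `bisse_comparison`: list with `models` (per-model table) and
#'   `lrt` (per-nested-pair table).
#' @export
compare_models <- function(fits, ...) {
  if (inherits(fits, "bisse_fit")) fits <- list(fits)
  fits <- c(fits, list(...))
  if (!all(vapply(fits, inherits, logical(1), "bisse_fit")))
    stop("all arguments must be bisse_fit objects")
  if (length(unique(vapply(fits, `[[`, integer(1), "n_tip"))) > 1L)
    stop("fits must be on the same data")
  n <- fits[[1]]$n_tip
  models <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, integer(1), "k"),
    lnL = vapply(fits, `[[`, numeric(1), "lnL"))
  models$AIC <- -2 * models$lnL + 2 * models$k
  models$AICc <- models$AIC +
    2 * models$k * (models$k + 1) / (n - models$k - 1)
  models$preferred <- models$AICc == min(models$AICc)
  lrt <- NULL
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i == j) next
    a <- fits[[i]]; b <- fits[[j]]
    if (a$k < b$k && is_nested(a$spec, b$spec)) {
      stat <- 2 * (b$lnL - a$lnL)
      df <- b$k - a$k
      lrt <- rbind(lrt, data.frame(
        constrained = a$model, general = b$model,
        statistic = stat, df = df,
        p_value = pchisq(max(stat, 0), df, lower.tail = FALSE)))
    }
  }
  out <- list(models = models, lrt = lrt)
  class(out) <- "bisse_comparison"
  out
}

#' @method print bisse_comparison
#' @export
print.bisse_comparison <- function(x, ...) {
  cat("Model comparison:\n")
  print(x$models, row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat("\nLikelihood-ratio tests:\n")
    print(x$lrt, row.names = FALSE)
  }
  invisible(x)
}

#' Fit BiSSE models across a set of replicate trees
#'
#' Fits each requested model on every tree (e.g. 100 topologies emulating a
#' posterior sample), recording per-tree parameter estimates and
#' likelihood-ratio statistics of each constrained model against the most
#' general one.  Individual tree failures are recorded, not fatal.  The
#' result carries the data behind the usual replicate histograms: net
#' diversification rates by state, and LRT statistics with chi-squared
#' reference lines at alpha = 0.05, 0.01 and 0.005.
#'
#' @param trees a `multiPhylo` object or list of trees (>= 2 for
#'   histograms; a single tree triggers a warning).
#' @param tips a [tip_data()] table (shared tip set across trees).
#' @param models character vector of model names; must include at least one
#'   pair with a nesting relation for LRT histograms.
#' @param ... passed to [fit_model()].
#' @return a `bisse_replicates` object: list with `fits` (long table of
#'   per-tree per-model estimates), `lrt` (per-tree statistics vs the most
#'   general model), `ref_lines` (chi-squared critical values), `failures`.
#' @export
replicate_analysis <- function(trees, tips, models = c("equal_div", "full"),
                               ...) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 2L)
    warning("fewer than 2 trees: replicate histograms are degenerate")
  specs <- lapply(models, model_spec)
  names(specs) <- models
  kmax <- which.max(vapply(specs, `[[`, integer(1), "k"))
  rows <- list(); lrt_rows <- list(); failures <- character(0)
  for (ti in seq_along(trees)) {
    fits <- list()
    for (m in models) {
      f <- tryCatch(fit_model(trees[[ti]], tips, model = m, ...),
                    error = function(e) e)
      if (inherits(f, "error")) {
        failures <- c(failures, sprintf("tree %d, %s: %s", ti, m,
                                        conditionMessage(f)))
        next
      }
      fits[[m]] <- f
      rows[[length(rows) + 1L]] <- data.frame(
        tree = ti, model = m, t(unclass(f$pars)), r0 = f$net_rates["r0"],
        r1 = f$net_rates["r1"], lnL = f$lnL, converged = f$converged,
        row.names = NULL)
    }
    gen <- models[kmax]
    if (!is.null(fits[[gen]])) {
      for (m in setdiff(names(fits), gen)) {
        if (!is_nested(specs[[m]], specs[[gen]])) next
        stat <- 2 * (fits[[gen]]$lnL - fits[[m]]$lnL)
        df <- specs[[gen]]$k - specs[[m]]$k
        lrt_rows[[length(lrt_rows) + 1L]] <- data.frame(
          tree = ti, constrained = m, general = gen, statistic = stat,
          df = df, p_value = pchisq(max(stat, 0), df, lower.tail = FALSE))
      }
    }
  }
  lrt <- if (length(lrt_rows)) do.call(rbind, lrt_rows) else NULL
  ref <- if (!is.null(lrt))
    data.frame(alpha = c(0.05, 0.01, 0.005),
               critical = stats::qchisq(1 - c(0.05, 0.01, 0.005),
                                        df = max(lrt$df)))
  else NULL
  out <- list(fits = do.call(rbind, rows), lrt = lrt, ref_lines = ref,
              failures = failures)
  class(out) <- "bisse_replicates"
  out
}

#' @method print bisse_replicates
#' @export
print.bisse_replicates <- function(x, ...) {
  nt <- length(unique(x$fits$tree))
  cat("BiSSE replicate analysis across", nt, "trees\n")
  if (!is.null(x$lrt))
    cat("  LRT rejections at 0.05:", sum(x$lrt$p_value < 0.05), "/",
        nrow(x$lrt), "\n")
  if (length(x$failures))
    cat("  failures:", length(x$failures), "\n")
  invisible(x)
}
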