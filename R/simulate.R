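## Forward (Gillespie) simulators for state-dependent and regime-shifted
## birth-death trees, genus-collapse of simulated trees, and node-age
## jittered replicate tree sets.  These generate inputs with the
## statistical structure the analyses assume, so every stage is testable
## without external data.

# internal: event-driven simulation of a binary-state birth-death process.
# Lineage bookkeeping arrays are grown by doubling; returns the raw lineage
# records plus the stopping time.
sim_two_state_core <- function(pars, max_age = NULL, max_tips = NULL,
                               root_state = 0L, root_split = TRUE) {
  l0 <- pars[1]; l1 <- pars[2]; m0 <- pars[3]; m1 <- pars[4]
  q01 <- pars[5]; q10 <- pars[6]
  cap <- 256L
  state <- integer(cap); start <- numeric(cap); end <- numeric(cap)
  fate <- integer(cap)   # 0 active/extant, 1 extinct, 2 split
  child1 <- integer(cap); child2 <- integer(cap)
  n_lin <- if (root_split) 2L else 1L
  state[seq_len(n_lin)] <- root_state
  active <- seq_len(n_lin)
  t <- 0
  grow <- function() {
    cap2 <- 2L * cap
    length(state) <<- cap2; length(start) <<- cap2; length(end) <<- cap2
    length(fate) <<- cap2; length(child1) <<- cap2; length(child2) <<- cap2
    state[(cap + 1L):cap2] <<- 0L; fate[(cap + 1L):cap2] <<- 0L
    cap <<- cap2
  }
  repeat {
    if (!length(active)) break
    st <- state[active]
    nA <- sum(st == 0L); nB <- length(active) - nA
    rates <- c(nA * l0, nA * m0, nA * q01, nB * l1, nB * m1, nB * q10)
    tot <- sum(rates)
    if (!is.null(max_tips) && length(active) >= max_tips) {
      ## cut at a uniform point of the sojourn interval at this tip count,
      ## so the final inter-event time is not truncated at an event
      if (tot > 0) t <- t + runif(1) * rexp(1, tot)
      break
    }
    if (tot <= 0) { t <- if (is.null(max_age)) t else max_age; break }
    dt <- rexp(1, tot)
    if (!is.null(max_age) && t + dt > max_age) { t <- max_age; break }
    t <- t + dt
    ev <- sample.int(6L, 1L, prob = rates)
    who_state <- if (ev <= 3L) 0L else 1L
    pool <- active[st == who_state]
    lin <- pool[sample.int(length(pool), 1L)]
    type <- (ev - 1L) %% 3L  # 0 birth, 1 death, 2 transition
    if (type == 2L) {
      state[lin] <- 1L - state[lin]
    } else if (type == 1L) {
      end[lin] <- t; fate[lin] <- 1L
      active <- active[active != lin]
    } else {
      while (n_lin + 2L > cap) grow()
      c1 <- n_lin + 1L; c2 <- n_lin + 2L; n_lin <- n_lin + 2L
      state[c(c1, c2)] <- state[lin]
      start[c(c1, c2)] <- t
      end[lin] <- t; fate[lin] <- 2L
      child1[lin] <- c1; child2[lin] <- c2
      active <- c(active[active != lin], c1, c2)
    }
  }
  end[active] <- t
  list(n = n_lin, state = state[seq_len(n_lin)], start = start[seq_len(n_lin)],
       end = end[seq_len(n_lin)], fate = fate[seq_len(n_lin)],
       child1 = child1[seq_len(n_lin)], child2 = child2[seq_len(n_lin)],
       t_final = t, n_extant = length(active), root_split = root_split)
}

# internal: lineage records -> phylo with all (extant + extinct) tips;
# simulations start from a root split, so lineages 1 and 2 attach to a
# synthetic root node
sim_to_phylo <- function(sim) {
  is_tip <- sim$fate != 2L
  ntip <- sum(is_tip)
  tip_id <- integer(sim$n); tip_id[is_tip] <- seq_len(ntip)
  nnode_internal <- sum(!is_tip) + 1L
  node_id <- integer(sim$n)
  node_id[!is_tip] <- ntip + 1L + seq_len(sum(!is_tip))
  num <- ifelse(is_tip, tip_id, node_id)
  root <- ntip + 1L
  parent_num <- rep(root, sim$n)
  for (i in seq_len(sim$n)) {
    if (sim$fate[i] == 2L) {
      parent_num[sim$child1[i]] <- num[i]
      parent_num[sim$child2[i]] <- num[i]
    }
  }
  edge <- cbind(parent_num, num)
  phy <- list(edge = edge, edge.length = sim$end - sim$start,
              tip.label = paste0("t", seq_len(ntip)),
              Nnode = nnode_internal)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  list(phy = phy, tip_state = sim$state[is_tip],
       tip_extant = sim$fate[is_tip] == 0L,
       tip_lineage = which(is_tip))
}

#' Simulate a tree under the binary-state speciation-extinction process
#'
#' Forward Gillespie simulation with state-dependent speciation, extinction
#' and transition rates, started from a root split (two lineages in
#' `root_state`, matching reconstructed-tree conventions).  The run stops
#' at `max_age` My (giving that root age) or when `max_tips` extant
#' lineages are reached.  Extinct lineages are pruned; tips are then kept
#' independently with probability `f`.  Replicates in which fewer than two
#' tips survive (or only one side of the root) are re-simulated by
#' continuing the random stream, up to `retries` times.
#'
#' @param pars a [bisse_params()] vector; defaults emulate the PACMAD-scale
#'   full-model rates (see the package vignette).
#' @param max_age stopping age in My (one of `max_age`, `max_tips`).
#' @param max_tips stopping extant tip count.
#' @param root_state state at the root (0 or 1).
#' @param f Bernoulli tip sampling fraction in (0, 1].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param retries resimulation cap on total extinction.
#' @return list with `tree` (ultrametric `phylo`), `tips` (a [tip_data()]
#'   table in proportional mode with fraction `f`) and `n_attempts`.
#' @export
simulate_bisse_tree <- function(pars = bisse_params(0.6924, 0.5667, 0.5539,
                                                    0.3267, 0.0068, 1e-4),
                                max_age = NULL, max_tips = NULL,
                                root_state = 0L, f = 1, seed = NULL,
                                retries = 1000L) {
  if (is.null(max_age) && is.null(max_tips))
    stop("give max_age or max_tips")
  if (!is.null(seed)) set.seed(seed)
  p6 <- as_pars6(pars)
  for (attempt in seq_len(retries)) {
    sim <- sim_two_state_core(p6, max_age, max_tips, root_state,
                              root_split = TRUE)
    if (sim$n_extant < 2L) next
    built <- sim_to_phylo(sim)
    extant <- built$phy$tip.label[built$tip_extant]
    if (length(extant) < 2L) next
    phy <- ape::keep.tip(built$phy, extant)
    states <- built$tip_state[built$tip_extant]
    names(states) <- extant
    if (!is.null(max_age) && abs(root_age(phy) - max_age) > 1e-8 * max_age)
      next  # one root side died out entirely
    if (f < 1) {
      keep <- extant[runif(length(extant)) < f]
      if (length(keep) < 2L) next
      phy <- ape::keep.tip(phy, keep)
      states <- states[keep]
    }
    td <- tip_data(phy$tip.label, states[phy$tip.label],
                   mode = "proportional", f = f)
    return(list(tree = as_timetree(phy), tips = td, n_attempts = attempt))
  }
  stop("simulation failed to produce a surviving tree within retry cap")
}

#' Simulate a constant-rate tree with one planted rate shift
#'
#' Single-character birth-death Gillespie simulation under a base
#' [bd_regime()]; at `shift_age` My before the end of the run, one extant
#' lineage (chosen uniformly) switches to `shift_regime`, and its
#' descendants inherit the new rates.  Returns the pruned extant tree plus
#' the ground truth needed for shift-recovery power tests.
#'
#' @param base_regime,shift_regime [bd_regime()] objects.  With
#'   `shift_regime = NULL` no shift is planted and the function reduces to
#'   a constant-rate simulator.
#' @param max_age run length in My (root age of surviving trees).
#' @param shift_age age (My before present) at which the shift occurs.
#' @param min_shift_tips minimum surviving tips in the shifted clade
#'   (replicates below this are re-simulated).
#' @param seed optional integer seed.
#' @param retries resimulation cap.
#' @return list with `tree`, `shift_tips` (labels of surviving shifted
#'   tips), `shift_edge` (index into `tree$edge` of the stem branch of the
#'   shifted clade, `NA` when no shift), `shift_age`, `n_attempts`.
#' @export
simulate_piecewise_bd <- function(base_regime, max_age, shift_regime = NULL,
                                  shift_age = NULL, min_shift_tips = 1L,
                                  seed = NULL, retries = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  has_shift <- !is.null(shift_regime)
  if (has_shift && (is.null(shift_age) || shift_age <= 0 ||
                    shift_age >= max_age))
    stop("shift_age must lie strictly inside (0, max_age)")
  for (attempt in seq_len(retries)) {
    res <- sim_piecewise_core(base_regime, shift_regime,
                              if (has_shift) max_age - shift_age else NULL,
                              max_age)
    if (res$sim$n_extant < 2L) next
    built <- sim_to_phylo(res$sim)
    extant <- built$phy$tip.label[built$tip_extant]
    if (length(extant) < 2L) next
    phy <- ape::keep.tip(built$phy, extant)
    if (abs(root_age(phy) - max_age) > 1e-8 * max_age) next
    shift_tips <- character(0); shift_edge <- NA_integer_
    if (has_shift) {
      if (is.na(res$shift_lineage)) next
      desc <- lineage_descendants(res$sim, res$shift_lineage)
      shift_tips <- intersect(built$phy$tip.label[built$tip_lineage %in% desc],
                              extant)
      if (length(shift_tips) < min_shift_tips) next
      shift_edge <- stem_edge_of(phy, shift_tips)
    }
    return(list(tree = as_timetree(phy), shift_tips = shift_tips,
                shift_edge = shift_edge, shift_age = shift_age,
                n_attempts = attempt))
  }
  stop("piecewise simulation failed within retry cap")
}

# core loop for the piecewise simulator: a two-"state" run where state 1 is
# the shifted regime and the state switch happens deterministically at
# shift_time by marking one extant lineage
sim_piecewise_core <- function(base, shift, shift_time, max_age) {
  b <- c(base$lambda, if (is.null(shift)) 0 else shift$lambda,
         base$mu, if (is.null(shift)) 0 else shift$mu, 0, 0)
  cap <- 256L
  state <- integer(cap); start <- numeric(cap); end <- numeric(cap)
  fate <- integer(cap); child1 <- integer(cap); child2 <- integer(cap)
  n_lin <- 2L; active <- 1:2; t <- 0
  shift_lineage <- NA_integer_
  shifted <- is.null(shift_time)
  grow <- function() {
    cap2 <- 2L * cap
    length(state) <<- cap2; length(start) <<- cap2; length(end) <<- cap2
    length(fate) <<- cap2; length(child1) <<- cap2; length(child2) <<- cap2
    state[(cap + 1L):cap2] <<- 0L; fate[(cap + 1L):cap2] <<- 0L
    cap <<- cap2
  }
  repeat {
    if (!length(active)) break
    st <- state[active]
    nA <- sum(st == 0L); nB <- length(active) - nA
    rates <- c(nA * b[1], nA * b[3], nB * b[2], nB * b[4])
    tot <- sum(rates)
    if (tot <= 0) { t <- max_age; break }
    dt <- rexp(1, tot)
    if (!shifted && t + dt > shift_time) {
      t <- shift_time
      shift_lineage <- active[sample.int(length(active), 1L)]
      state[shift_lineage] <- 1L
      shifted <- TRUE
      next
    }
    if (t + dt > max_age) { t <- max_age; break }
    t <- t + dt
    ev <- sample.int(4L, 1L, prob = rates)
    who_state <- if (ev <= 2L) 0L else 1L
    pool <- active[st == who_state]
    lin <- pool[sample.int(length(pool), 1L)]
    if (ev %in% c(2L, 4L)) {
      end[lin] <- t; fate[lin] <- 1L
      active <- active[active != lin]
    } else {
      while (n_lin + 2L > cap) grow()
      c1 <- n_lin + 1L; c2 <- n_lin + 2L; n_lin <- n_lin + 2L
      state[c(c1, c2)] <- state[lin]
      start[c(c1, c2)] <- t
      end[lin] <- t; fate[lin] <- 2L
      child1[lin] <- c1; child2[lin] <- c2
      active <- c(active[active != lin], c1, c2)
    }
  }
  end[active] <- t
  sim <- list(n = n_lin, state = state[seq_len(n_lin)],
              start = start[seq_len(n_lin)], end = end[seq_len(n_lin)],
              fate = fate[seq_len(n_lin)], child1 = child1[seq_len(n_lin)],
              child2 = child2[seq_len(n_lin)], t_final = t,
              n_extant = length(active), root_split = TRUE)
  list(sim = sim, shift_lineage = shift_lineage)
}

# all lineage indices descending from (and including) `lin`
lineage_descendants <- function(sim, lin) {
  out <- integer(0); stack <- lin
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    if (sim$fate[v] == 2L) stack <- c(stack, sim$child1[v], sim$child2[v])
  }
  out
}

# stem edge (row of phy$edge) of the clade spanned by `labels`
stem_edge_of <- function(phy, labels) {
  node <- if (length(labels) == 1L) match(labels, phy$tip.label)
          else ape::getMRCA(phy, labels)
  e <- which(phy$edge[, 2] == node)
  if (length(e)) e else NA_integer_  # clade spans the root
}

#' Collapse a simulated tree into genus-like unresolved blocks
#'
#' Partitions the tips into the maximal monophyletic blocks of at most
#' `block_cap` tips, keeps one representative per block (first label in the
#' block) carrying the block's summed richness, and reports the per-block
#' state tallies and stem ages.  This produces genus-level fixtures for the
#' shift analysis and the unresolved-clade BiSSE mode; total richness is
#' conserved exactly.
#'
#' @param phy a `phylo` object (typically simulated).
#' @param tips a [tip_data()] table for its tips.
#' @param block_cap maximum tips per block (>= 1); `1` is the identity.
#' @return list with `tree`, `tips` (unresolved-mode [tip_data()]),
#'   `richness` (data.frame `tip_label`, `stem_age`, `richness`, `n0`,
#'   `n1`) and `blocks` (membership list).
#' @export
collapse_simulated_genera <- function(phy, tips, block_cap) {
  if (block_cap < 1L) stop("block_cap must be >= 1")
  tips <- match_tips(tips, phy)
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  cnt <- integer(ntot); cnt[seq_len(ntip)] <- 1L
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge)))
    cnt[po$edge[k, 1]] <- cnt[po$edge[k, 1]] + cnt[po$edge[k, 2]]
  parent <- integer(ntot); parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  if (cnt[root] <= block_cap)
    stop("block_cap must be smaller than the number of tips")
  parent[root] <- root  # sentinel: cnt[root] > block_cap keeps root eligible
  block_nodes <- which(cnt <= block_cap & cnt[parent] > block_cap)
  blocks <- lapply(block_nodes, function(v) {
    if (v <= ntip) phy$tip.label[v] else ape::extract.clade(phy, v)$tip.label
  })
  reps <- vapply(blocks, function(b) sort(b)[1], character(1))
  st <- setNames(tips$state, tips$tip_label)
  rich <- setNames(tips$richness, tips$tip_label)
  n0 <- vapply(blocks, function(b) sum(st[b] == 0L, na.rm = TRUE), integer(1))
  n1 <- vapply(blocks, function(b) sum(st[b] == 1L, na.rm = TRUE), integer(1))
  brich <- vapply(blocks, function(b) sum(rich[b]), numeric(1))
  bstate <- ifelse(n1 > 0L & n0 == 0L, 1L, ifelse(n0 > 0L & n1 == 0L, 0L,
                                                  NA_integer_))
  tree2 <- ape::keep.tip(phy, reps)
  tips2 <- match_tips(tip_data(reps, bstate, brich, mode = "unresolved",
                               f = 1), tree2)
  rd <- richness_data(tree2, tips2)
  rd$n0 <- n0[match(rd$tip_label, reps)]
  rd$n1 <- n1[match(rd$tip_label, reps)]
  names(blocks) <- reps
  list(tree = tree2, tips = tips2, richness = rd, blocks = blocks)
}

#' Jittered replicate tree set
#'
#' Produces `n_replicates` ultrametric variants of a tree by perturbing the
#' relative position of every internal node between the present and its
#' parent's (already jittered) age: a stand-in for posterior tree samples
#' in replicate analyses.  The root age is preserved exactly; parent-child
#' age ordering is preserved by construction, and `jitter = 0` returns
#' identical copies.
#'
#' @param phy an ultrametric `phylo` object.
#' @param n_replicates number of trees.
#' @param jitter standard deviation of the perturbation of each node's
#'   relative depth (dimensionless; ~0.02-0.1 is mild).
#' @param seed optional integer seed.
#' @return a `multiPhylo` object.
#' @export
perturb_tree_set <- function(phy, n_replicates, jitter = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- as_timetree(phy)
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  age <- node_ages(phy)
  parent <- integer(ntot); parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  inner <- setdiff(which(seq_len(ntot) > ntip), root)
  inner <- inner[order(-age[inner])]  # parents before children
  out <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    new_age <- age
    for (v in inner) {
      u <- age[v] / age[parent[v]]
      u2 <- pmin(pmax(u + rnorm(1, 0, jitter), 1e-3), 1 - 1e-3)
      if (jitter == 0) u2 <- u
      new_age[v] <- u2 * new_age[parent[v]]
    }
    t2 <- phy
    t2$edge.length <- new_age[phy$edge[, 1]] - new_age[phy$edge[, 2]]
    out[[rep_i]] <- t2
  }
  class(out) <- "multiPhylo"
  out
}
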