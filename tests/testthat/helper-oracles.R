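# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's own code paths: a fixed-step RK4 integrator for the BiSSE
# ODEs, an R-level post-order likelihood built on it, brute-force tree
# traversals, and textbook constant-rate birth-death closed forms.

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

cherry <- function() ape::read.tree(text = "(A:1,B:1);")

# fixed-step RK4 for the four BiSSE ODEs (E0, E1, D0, D1)
rk4_bisse <- function(y, pars, len, h = 1e-3) {
  pars <- unname(pars); y <- unname(y)
  deriv <- function(y) {
    l0 <- pars[1]; l1 <- pars[2]; m0 <- pars[3]; m1 <- pars[4]
    q01 <- pars[5]; q10 <- pars[6]
    c(m0 - (l0 + m0 + q01) * y[1] + q01 * y[2] + l0 * y[1]^2,
      m1 - (l1 + m1 + q10) * y[2] + q10 * y[1] + l1 * y[2]^2,
      -(l0 + m0 + q01) * y[3] + q01 * y[4] + 2 * l0 * y[1] * y[3],
      -(l1 + m1 + q10) * y[4] + q10 * y[3] + 2 * l1 * y[2] * y[4])
  }
  if (len == 0) return(y)
  n <- max(1L, ceiling(len / h))
  hh <- len / n
  for (i in seq_len(n)) {
    k1 <- deriv(y); k2 <- deriv(y + hh / 2 * k1)
    k3 <- deriv(y + hh / 2 * k2); k4 <- deriv(y + hh * k3)
    y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# R-level post-order BiSSE log-likelihood on the RK4 oracle, log-scale
# factors accumulated at nodes; proportional sampling only
bisse_loglik_oracle <- function(phy, states, pars, f = 1,
                                root_mode = "weighted", root_state = NULL,
                                h = 1e-3) {
  ntip <- ape::Ntip(phy)
  po <- ape::reorder.phylo(phy, "postorder")
  Y <- matrix(NA_real_, ntip + phy$Nnode, 4)
  lf <- numeric(ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    s <- states[phy$tip.label[i]]
    D <- if (is.na(s)) c(f, f) else if (s == 0) c(f, 0) else c(0, f)
    Y[i, ] <- c(1 - f, 1 - f, D)
  }
  seen <- logical(ntip + phy$Nnode)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    y <- Y[ch, ]
    if (ch > ntip) y[3:4] <- pars[1:2] * y[3:4]
    y <- rk4_bisse(y, pars, po$edge.length[k], h)
    m <- max(y[3:4])
    y[3:4] <- y[3:4] / m
    if (!seen[p]) {
      Y[p, ] <- y; lf[p] <- lf[ch] + log(m); seen[p] <- TRUE
    } else {
      Y[p, 3:4] <- Y[p, 3:4] * y[3:4]
      lf[p] <- lf[p] + lf[ch] + log(m)
    }
  }
  root <- ntip + 1L
  D <- pars[1:2] * Y[root, 3:4]
  w <- switch(root_mode,
              weighted = D / sum(D),
              flat = c(0.5, 0.5),
              given = if (root_state == 0) c(1, 0) else c(0, 1))
  log(sum(w * D)) + lf[root]
}

# textbook constant-rate birth-death reconstructed-tree log-likelihood
# (complete sampling, no conditioning, speciation factor at every internal
# node including the root)
bd_loglik_closed <- function(phy, lambda, mu) {
  r <- lambda - mu; eps <- mu / lambda
  lnpsi <- function(t) {
    b <- expm1(r * t) / (expm1(r * t) + 1 - eps)
    log1p(-eps * b) + log1p(-b)
  }
  age <- divergrass::node_ages(phy)
  t_old <- age[phy$edge[, 1]]; t_young <- age[phy$edge[, 2]]
  (ape::Ntip(phy) - 1) * log(lambda) + sum(lnpsi(t_old) - lnpsi(t_young))
}

# brute-force node ages by summing branch lengths root -> node
ages_brute <- function(phy) {
  ntot <- ape::Ntip(phy) + phy$Nnode
  parent <- integer(ntot); blen <- numeric(ntot)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen[phy$edge[, 2]] <- phy$edge.length
  depth <- numeric(ntot)
  for (v in seq_len(ntot)) {
    d <- 0; u <- v
    while (parent[u] != 0) { d <- d + blen[u]; u <- parent[u] }
    depth[v] <- d
  }
  max(depth) - depth
}

# brute-force sister-pair count: for every node, check whether one child
# clade is pure state-1 and the other pure state-0
sister_pairs_brute <- function(phy, states) {
  ntip <- ape::Ntip(phy)
  count <- 0L
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    if (length(kids) != 2L) next
    stset <- lapply(kids, function(k) {
      labs <- if (k <= ntip) phy$tip.label[k]
              else ape::extract.clade(phy, k)$tip.label
      states[labs]
    })
    pure1 <- vapply(stset, function(s) all(!is.na(s)) && all(s == 1),
                    logical(1))
    pure0 <- vapply(stset, function(s) all(!is.na(s)) && all(s == 0),
                    logical(1))
    if ((pure1[1] && pure0[2]) || (pure1[2] && pure0[1])) count <- count + 1L
  }
  count
}

random_pars <- function() {
  divergrass::bisse_params(runif(1, .1, .6), runif(1, .1, .6),
                           runif(1, 0, .3), runif(1, 0, .3),
                           runif(1, .01, .1), runif(1, .01, .1))
}

swap_pars <- function(p) {
  v <- unname(unclass(p))  # lambda0 lambda1 mu0 mu1 q01 q10
  divergrass::bisse_params(v[2], v[1], v[4], v[3], v[6], v[5])
}
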