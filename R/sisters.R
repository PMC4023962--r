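## Sister-clade richness contrasts: find derived-state (C4) clades whose
## sister clades are entirely ancestral-state (C3), then compare log-scale
## species richness with an exact Wilcoxon signed-rank test.

#' Extract derived-state clades with pure ancestral-state sisters
#'
#' Under irreversible-gain parsimony, each origin of the derived state is
#' the MRCA of a maximal connected set of state-1 tips.  For every such
#' origin whose sister clade contains only state-0 tips (no state-1, no
#' unknown-state tips), returns the pair of summed richnesses.
#'
#' @param phy a rooted `phylo` object.
#' @param tips a [tip_data()] table with states and richness.
#' @return a data.frame with one row per pair: `focal` (a representative
#'   label of the derived clade), `focal_tips`, `focal_richness`, `sister`,
#'   `sister_tips`, `sister_richness`; attribute `n_origins` counts all
#'   derived-state origins.
#' @export
extract_pairs <- function(phy, tips) {
  tips <- match_tips(tips, phy)
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  st <- tips$state
  if (!any(!is.na(st) & st == 1L)) stop("tree has no derived-state (1) tips")
  n1 <- integer(ntot); n0 <- integer(ntot); nna <- integer(ntot)
  rich <- numeric(ntot)
  n1[seq_len(ntip)] <- as.integer(!is.na(st) & st == 1L)
  n0[seq_len(ntip)] <- as.integer(!is.na(st) & st == 0L)
  nna[seq_len(ntip)] <- as.integer(is.na(st))
  rich[seq_len(ntip)] <- tips$richness
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    n1[p] <- n1[p] + n1[ch]; n0[p] <- n0[p] + n0[ch]
    nna[p] <- nna[p] + nna[ch]; rich[p] <- rich[p] + rich[ch]
  }
  ntips_below <- n1 + n0 + nna
  parent <- integer(ntot)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  parent[root] <- root
  all1 <- n1 == ntips_below & n1 > 0L
  ## origins: maximal all-derived clades
  origin <- which(all1 & (seq_len(ntot) == root | !all1[parent]))
  first_tip <- function(v) {
    if (v <= ntip) phy$tip.label[v]
    else ape::extract.clade(phy, v)$tip.label[1]
  }
  rows <- list()
  for (v in origin) {
    if (v == root) next                      # whole tree derived: no sister
    p <- parent[v]
    sib <- setdiff(phy$edge[phy$edge[, 1] == p, 2], v)
    if (length(sib) != 1L) next              # polytomy: sister ill-defined
    if (n1[sib] > 0L || nna[sib] > 0L || n0[sib] == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      focal = first_tip(v), focal_tips = ntips_below[v],
      focal_richness = rich[v],
      sister = first_tip(sib), sister_tips = ntips_below[sib],
      sister_richness = rich[sib], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(focal = character(0), focal_tips = integer(0),
                         focal_richness = numeric(0), sister = character(0),
                         sister_tips = integer(0),
                         sister_richness = numeric(0))
  attr(out, "n_origins") <- length(origin)
  out
}

# exact null distribution of the signed-rank statistic W+ over all 2^n sign
# patterns, by convolution over the (doubled, integerized) midranks;
# returns P(W+ = w) on the doubled scale 0..sum(ranks2)
signed_rank_null <- function(ranks2) {
  tot <- sum(ranks2)
  p <- numeric(tot + 1L)
  p[1] <- 1
  for (w in ranks2) {
    shifted <- c(rep(0, w), p[seq_len(tot + 1L - w)])
    p <- (p + shifted) / 2
  }
  p
}

#' Exact Wilcoxon signed-rank test on log richness of sister pairs
#'
#' Tests whether `log(focal richness) - log(sister richness)` is centred at
#' zero across pairs.  Zero differences are dropped (with `n` reduced);
#' tied absolute differences receive midranks.  For `n <= exact_limit`
#' pairs the null distribution of the signed-rank sum `V` is exact
#' (enumeration of all sign patterns, by convolution); above that, a normal
#' approximation with continuity and tie correction is used.  The p-value
#' is invariant to the logarithm base and to rescaling all richnesses by a
#' positive constant, since signs and ranks are unchanged.
#'
#' @param pairs a data.frame from [extract_pairs()] (columns
#'   `focal_richness`, `sister_richness`), or a numeric vector of
#'   differences via `diffs`.
#' @param diffs optional numeric vector of paired differences, overriding
#'   `pairs`.
#' @param exact_limit largest `n` for which the exact distribution is used
#'   (default 25).
#' @return a list with `statistic` (V, the positive-rank sum), `n_used`,
#'   `p_greater`, `p_less` (one-sided), `p_two_sided`, and `method`.
#' @export
signed_rank_test <- function(pairs = NULL, diffs = NULL, exact_limit = 25L) {
  if (is.null(diffs)) {
    if (is.null(pairs) || nrow(pairs) < 1L) stop("need at least one pair")
    diffs <- log(pairs$focal_richness) - log(pairs$sister_richness)
  }
  d <- diffs[diffs != 0]
  if (!length(d)) stop("all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    null <- signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * V))
    idx <- seq_along(null) - 1L
    p_ge <- sum(null[idx >= w2])
    p_le <- sum(null[idx <= w2])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p_ge <- pnorm((V - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
    p_le <- pnorm((V + 0.5 - mu) / sqrt(sig2))
    method <- "normal approximation"
  }
  list(statistic = V, n_used = n, p_greater = p_ge, p_less = p_le,
       p_two_sided = min(1, 2 * min(p_ge, p_le)), method = method)
}

#' Run the full sister-contrast analysis
#'
#' Convenience wrapper: [extract_pairs()] then [signed_rank_test()].
#'
#' @inheritParams extract_pairs
#' @param ... passed to [signed_rank_test()].
#' @return list with `pairs` and `test`.
#' @export
sister_contrasts <- function(phy, tips, ...) {
  pairs <- extract_pairs(phy, tips)
  if (!nrow(pairs)) stop("no derived-state clades with pure sister clades")
  list(pairs = pairs, test = signed_rank_test(pairs, ...))
}
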