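## Composite-tree surgery and richness bookkeeping: rescaling separately
## calibrated subtrees, grafting them into a backbone, collapsing sampled
## trees to one representative per genus, and allocating unsampled species
## richness to tips.

#' Rescale a tree to a target root age
#'
#' Multiplies every branch length by `target / current root age`, the usual
#' way of reconciling separately calibrated subtrees with backbone node
#' ages.  Topology and all ratios of node ages are preserved.
#'
#' @param phy a `phylo` object.
#' @param target_root_age target root age in My (> 0).
#' @return the rescaled tree.
#' @export
scale_to_root_age <- function(phy, target_root_age) {
  if (!is.numeric(target_root_age) || target_root_age <= 0)
    stop("target root age must be > 0")
  ra <- root_age(phy)
  if (ra <= 0) stop("current root age is zero")
  phy$edge.length <- phy$edge.length * (target_root_age / ra)
  phy
}

#' Graft a calibrated subtree onto a backbone at a placeholder clade
#'
#' The backbone marks the attachment point with a pair of placeholder tips
#' that must form a cherry (a monophyletic pair).  The placeholder clade is
#' replaced by `subtree`, rescaled so its crown sits at `target_crown_age`,
#' attached on the same stem.  The result is ultrametric, with
#' `Ntip(backbone) - 2 + Ntip(subtree)` tips, and every backbone node age
#' outside the replaced clade unchanged.
#'
#' @param backbone an ultrametric `phylo` object.
#' @param placeholders character vector of the two placeholder tip labels.
#' @param subtree an ultrametric `phylo` object to insert.
#' @param target_crown_age crown age for the inserted clade; must be smaller
#'   than the placeholder clade's stem age.  Defaults to the subtree's
#'   current root age.
#' @return the composite tree.
#' @export
graft <- function(backbone, placeholders, subtree,
                  target_crown_age = root_age(subtree)) {
  if (length(placeholders) != 2L)
    stop("exactly two placeholder tip labels are required")
  info <- mrca_and_clade(backbone, placeholders)
  if (ape::Ntip(info$subtree) != 2L)
    stop("placeholder pair is not monophyletic (not a cherry)")
  if (info$is_root) stop("placeholder clade cannot be the whole tree")
  if (target_crown_age >= info$stem_age)
    stop(sprintf("target crown age (%.4g) must be below the stem age (%.4g)",
                 target_crown_age, info$stem_age))
  sub <- scale_to_root_age(subtree, target_crown_age)
  sub$root.edge <- NULL
  bb <- ape::drop.tip(backbone, placeholders[2])
  i <- which(bb$tip.label == placeholders[1])
  e <- which(bb$edge[, 2] == i)
  ## bind.tree() hangs the subtree root at the end of this pendant edge, so
  ## shorten it to reach exactly from the stem down to the target crown age
  bb$edge.length[e] <- info$stem_age - target_crown_age
  out <- ape::bind.tree(bb, sub, where = i)
  as_timetree(out)
}

#' Largest-remainder integer division
#'
#' Splits `total` into `k` integer shares that sum exactly to `total`, as
#' close to equal as possible: floor shares plus one extra unit for the
#' first `total mod k` shares (e.g. 550 into 3 gives 184, 183, 183).  Used
#' wherever species richness must be divided evenly among representatives,
#' since the birth--death richness likelihoods need integer counts.
#'
#' @param total non-negative integer to divide.
#' @param k number of shares.
#' @return integer vector of length `k` summing to `total`.
#' @export
largest_remainder <- function(total, k) {
  if (k < 1L) stop("k must be >= 1")
  base <- total %/% k
  extra <- total %% k
  as.integer(base + (seq_len(k) <= extra))
}

# allocate `total` among groups proportionally to `weights`, integer output
# summing to total (largest remainder on the fractional parts)
proportional_allocation <- function(total, weights) {
  if (length(weights) == 1L) return(as.integer(total))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# genus of each tip: explicit map wins, else the label prefix before "_"
tip_genus <- function(labels, genus_map = NULL) {
  if (!is.null(genus_map)) {
    g <- genus_map[labels]
    if (anyNA(g)) stop("genus map missing for: ",
                       paste(head(labels[is.na(g)], 5), collapse = ", "))
    unname(g)
  } else sub("_.*$", "", labels)
}

# maximal state-pure monophyletic blocks among a set of tips, computed on
# the subtree induced by those tips; returns a list of character vectors
pure_blocks <- function(phy, labels, states) {
  if (length(labels) == 1L) return(list(labels))
  sub <- ape::keep.tip(phy, labels)
  st <- states[match(sub$tip.label, labels)]
  ntip <- ape::Ntip(sub)
  key <- ifelse(is.na(st), "na", as.character(st))
  node_key <- character(ntip + sub$Nnode)
  node_key[seq_len(ntip)] <- key
  po <- ape::reorder.phylo(sub, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    node_key[p] <- if (node_key[p] == "") node_key[ch]
                   else if (node_key[p] == node_key[ch]) node_key[ch]
                   else "mixed"
  }
  parent <- integer(ntip + sub$Nnode)
  parent[sub$edge[, 2]] <- sub$edge[, 1]
  root <- ntip + 1L
  is_block <- function(v) node_key[v] != "mixed" &&
    (v == root || node_key[parent[v]] == "mixed")
  blocks <- list()
  for (v in seq_len(ntip + sub$Nnode)) {
    if (is_block(v)) {
      tips_v <- if (v <= ntip) sub$tip.label[v]
                else ape::extract.clade(sub, v)$tip.label
      blocks[[length(blocks) + 1L]] <- tips_v
    }
  }
  blocks
}

#' Collapse a sampled tree to genus representatives with assigned richness
#'
#' Implements the richness-assignment rules used to build genus-level trees
#' for diversification analysis:
#'
#' * each genus keeps one representative tip carrying the genus's total
#'   species richness (representative chosen by `policy`);
#' * genera mixing both character states are divided into the minimum
#'   number of state-pure monophyletic blocks, one representative each,
#'   with richness allocated to states/blocks by known per-state totals
#'   (columns `size_c3`, `size_c4` of `richness_table`) or, failing that,
#'   proportionally to sampled tip counts;
#' * genera larger than `split_threshold` species are split among
#'   `ceiling(size / split_threshold)` representatives with richness divided
#'   evenly (largest-remainder integerization), so that very large clades do
#'   not hang on single short branches;
#' * genera listed in `spread_genera` (known polyphyletic genera, e.g.
#'   Panicum) first have their total spread equally among all their sampled
#'   tips, then their monophyletic blocks are collapsed with summed shares.
#'
#' Total assigned richness is conserved exactly by every rule.
#'
#' @param phy a `phylo` object whose tip labels encode genus as the prefix
#'   before `"_"` (or supply `genus_map`).
#' @param tips a [tip_data()] table for the sampled tips.
#' @param richness_table data.frame with columns `genus`, `size` and
#'   optionally `size_c3`, `size_c4`; every sampled genus must appear.
#' @param split_threshold genus size above which the genus is split among
#'   several representatives (default 190 species).
#' @param spread_genera character vector of genera whose richness is spread
#'   equally across all their tips before collapsing.
#' @param genus_map optional named character vector tip label -> genus.
#' @param policy representative choice; `"first"` (lexicographically first
#'   label, the deterministic default) or a function(labels) -> label.
#' @return a list with `tree` (collapsed tree), `tips` (new [tip_data()]
#'   with representative richness and states) and `blocks` (bookkeeping
#'   data.frame: representative, genus, block size, richness).
#' @export
collapse_to_representatives <- function(phy, tips, richness_table,
                                        split_threshold = 190L,
                                        spread_genera = character(),
                                        genus_map = NULL,
                                        policy = "first") {
  if (split_threshold <= 0) stop("split threshold must be > 0")
  tips <- match_tips(tips, phy)
  pick <- if (is.function(policy)) policy else function(l) sort(l)[1]
  genus <- tip_genus(tips$tip_label, genus_map)
  known <- richness_table$genus
  miss <- setdiff(unique(genus), known)
  if (length(miss))
    stop("richness table missing genus: ", paste(head(miss, 5), collapse = ", "))
  rep_label <- character(0); rep_state <- integer(0); rep_rich <- integer(0)
  rep_genus <- character(0); rep_block_n <- integer(0)
  add <- function(label, state, rich, g, bn) {
    rep_label <<- c(rep_label, label); rep_state <<- c(rep_state, state)
    rep_rich <<- c(rep_rich, as.integer(rich)); rep_genus <<- c(rep_genus, g)
    rep_block_n <<- c(rep_block_n, as.integer(bn))
  }
  for (g in unique(genus)) {
    sel <- genus == g
    labs <- tips$tip_label[sel]
    sts <- tips$state[sel]
    size <- richness_table$size[match(g, known)]
    if (size < 1) stop("genus size must be >= 1: ", g)
    if (g %in% spread_genera) {
      share <- largest_remainder(size, length(labs))
      names(share) <- labs
      blocks <- pure_blocks(phy, labs, sts)
      for (b in blocks) {
        st <- sts[match(b[1], labs)]
        add(pick(b), st, sum(share[b]), g, length(b))
      }
    } else if (length(unique(na.omit(sts))) > 1L) {
      blocks <- pure_blocks(phy, labs, sts)
      bst <- vapply(blocks, function(b) sts[match(b[1], labs)], integer(1))
      if (!is.null(richness_table$size_c3) &&
          !is.na(richness_table$size_c3[match(g, known)])) {
        tot <- c(`0` = richness_table$size_c3[match(g, known)],
                 `1` = richness_table$size_c4[match(g, known)])
        if (sum(tot) != size) stop("per-state sizes do not sum to size for ", g)
      } else {
        cnt <- c(sum(sts == 0, na.rm = TRUE), sum(sts == 1, na.rm = TRUE))
        tot <- setNames(proportional_allocation(size, cnt), c("0", "1"))
      }
      for (s in c(0L, 1L)) {
        bs <- which(bst == s)
        if (!length(bs)) {
          if (tot[as.character(s)] > 0)
            stop("mixed-state genus ", g, " has richness for state ", s,
                 " but no sampled block of that state")
          next
        }
        w <- vapply(blocks[bs], length, integer(1))
        alloc <- proportional_allocation(tot[as.character(s)], w)
        for (j in seq_along(bs))
          add(pick(blocks[[bs[j]]]), s, alloc[j], g, w[j])
      }
    } else {
      st <- if (all(is.na(sts))) NA_integer_ else unique(na.omit(sts))
      if (size > split_threshold) {
        k <- min(ceiling(size / split_threshold), length(labs))
        reps <- sort(labs)[seq_len(k)]
        shares <- largest_remainder(size, k)
        for (j in seq_len(k)) add(reps[j], st, shares[j], g, length(labs))
      } else {
        add(pick(labs), st, size, g, length(labs))
      }
    }
  }
  out_tree <- ape::keep.tip(phy, rep_label)
  out_tips <- tip_data(rep_label, rep_state, rep_rich,
                       mode = "unresolved", f = 1)
  out_tips <- match_tips(out_tips, out_tree)
  list(tree = out_tree, tips = out_tips,
       blocks = data.frame(representative = rep_label, genus = rep_genus,
                           sampled_tips = rep_block_n, richness = rep_rich,
                           state = rep_state, stringsAsFactors = FALSE))
}

#' Report assigned richness, coverage and sampling-fraction consistency
#'
#' @param tips a [tip_data()] table.
#' @param known_total optional known total species richness of the group,
#'   for a coverage fraction.
#' @return a list with `n_tips`, `assigned` (sum of tip richness),
#'   `coverage` (`assigned / known_total`), and `f_implied`
#'   (`n_tips / assigned`, the sampling fraction implied by treating each
#'   tip as one sampled species).
#' @export
validate_assignment <- function(tips, known_total = NULL) {
  assigned <- sum(tips$richness)
  list(n_tips = nrow(tips), assigned = assigned,
       coverage = if (is.null(known_total)) NA_real_ else assigned / known_total,
       f_implied = nrow(tips) / assigned,
       f_recorded = attr(tips, "f"))
}

#' Stem ages and richness data for terminally unresolved tips
#'
#' Builds the `(tip, stem age, richness)` records consumed by the piecewise
#' birth--death shift analysis and by the unresolved-clade BiSSE mode.
#'
#' @param phy a `phylo` object.
#' @param tips a [tip_data()] table.
#' @return data.frame with columns `tip_label`, `stem_age`, `richness`,
#'   `state`.
#' @export
richness_data <- function(phy, tips) {
  tips <- match_tips(tips, phy)
  age <- node_ages(phy)
  parent <- phy$edge[match(seq_len(ape::Ntip(phy)), phy$edge[, 2]), 1]
  data.frame(tip_label = tips$tip_label, stem_age = age[parent],
             richness = tips$richness, state = tips$state,
             stringsAsFactors = FALSE)
}
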