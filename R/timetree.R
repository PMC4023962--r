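## Tree data model shared by every analysis stage.
##
## A "time tree" here is an ape `phylo` object that is rooted, has branch
## lengths in My, non-negative edge lengths, unique tip labels and tips that
## all sit at age 0 (ultrametric within tolerance).  Ages are measured
## backward from the present, so the root has the largest age.

#' Node ages of a time-calibrated tree
#'
#' Ages are in My before present: every tip of an ultrametric tree has age 0
#' and the root has the largest age.  For non-ultrametric input, age is
#' measured from the most distant tip.
#'
#' @param phy a `phylo` object with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed like `phy$edge`.
#' @export
node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

#' Root age of a tree
#' @param phy a `phylo` object.
#' @return root age in My.
#' @export
root_age <- function(phy) max(ape::node.depth.edgelength(phy))

#' Validate (and optionally repair) a time-calibrated tree
#'
#' Checks the invariants every downstream analysis assumes: rooted topology,
#' non-negative branch lengths, unique tip labels, and ultrametricity within
#' `tol_ultra` (default `1e-6 *` root age).  Polytomies are resolved into
#' bifurcations with zero-length branches (with a warning) because the
#' state-dependent likelihoods are defined on bifurcating trees.
#'
#' @param phy a `phylo` object.
#' @param tol_ultra absolute age tolerance for tips; default `1e-6 * root age`.
#' @param force_ultrametrize if `TRUE`, tips off the present by more than
#'   `tol_ultra` are repaired by adjusting their pendant branch so the tip
#'   sits exactly at age 0; if `FALSE` (default) such trees are rejected.
#' @return a validated `phylo` object (possibly with resolved polytomies).
#' @export
as_timetree <- function(phy, tol_ultra = NULL, force_ultrametrize = FALSE) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (!ape::is.binary(phy)) {
    warning("polytomies resolved arbitrarily with zero-length branches")
    phy <- ape::multi2di(phy, random = FALSE)
  }
  ra <- root_age(phy)
  if (ra <= 0) stop("root age must be > 0")
  if (is.null(tol_ultra)) tol_ultra <- 1e-6 * ra
  tip_ages <- node_ages(phy)[seq_len(ape::Ntip(phy))]
  if (any(tip_ages > tol_ultra)) {
    if (!force_ultrametrize) {
      stop(sprintf("tree is not ultrametric: max tip age %.3g exceeds tol %.3g",
                   max(tip_ages), tol_ultra))
    }
    pend <- match(seq_len(ape::Ntip(phy)), phy$edge[, 2])
    phy$edge.length[pend] <- phy$edge.length[pend] + tip_ages
    if (any(phy$edge.length < 0))
      stop("cannot ultrametrize: pendant branch would become negative")
  }
  phy
}

#' Read a time-calibrated tree from Newick or Nexus
#'
#' Multi-tree files (e.g. replicate sets emulating a posterior sample) are
#' indexed with `index`, which is 1-based: `index = 57` returns the 57th
#' tree in file order.
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"`.
#' @param index 1-based tree index for multi-tree files.
#' @param ... passed to [as_timetree()] (e.g. `force_ultrametrize`).
#' @return a validated `phylo` object.
#' @export
read_tree <- function(path, format = c("newick", "nexus"), index = 1L, ...) {
  format <- match.arg(format)
  trees <- switch(format,
                  newick = ape::read.tree(path),
                  nexus  = ape::read.nexus(path))
  if (is.null(trees)) stop("could not read tree from ", path)
  if (inherits(trees, "multiPhylo")) {
    if (index < 1L || index > length(trees))
      stop("tree index out of range: file has ", length(trees), " trees")
    trees <- trees[[index]]
  }
  as_timetree(trees, ...)
}

#' Write a tree (or set of trees) to Newick
#'
#' Branch lengths are written with enough digits for a lossless round trip;
#' internal node labels (used for regime annotations) are preserved.
#'
#' @param phy a `phylo` or `multiPhylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' Per-tip data table: state, richness, sampling mode
#'
#' Builds the tip table used by the state-dependent analyses.  `state` is 0
#' for the ancestral pathway (C3), 1 for the derived pathway (C4), `NA` for
#' unknown.  `richness` is the number of extant species each tip stands for
#' (1 for a fully resolved tip).  Two missing-diversity modes are supported:
#' `"proportional"` (a global sampling fraction `f` enters the tip initial
#' conditions) and `"unresolved"` (richness > 1 tips are treated as
#' terminally unresolved clades; `f` is then 1 because all species are
#' assigned to some tip).
#'
#' @param tip_label character vector of tip labels.
#' @param state integer vector in `{0, 1, NA}`.
#' @param richness positive integer vector of species counts per tip.
#' @param mode `"proportional"` or `"unresolved"`.
#' @param f global sampling fraction in (0, 1].
#' @return a `data.frame` with class `"tip_data"` and attributes `mode`, `f`.
#' @export
tip_data <- function(tip_label, state = NA_integer_, richness = 1L,
                     mode = c("proportional", "unresolved"), f = 1) {
  mode <- match.arg(mode)
  n <- length(tip_label)
  state <- rep_len(as.integer(state), n)
  richness <- rep_len(as.integer(richness), n)
  if (anyDuplicated(tip_label)) stop("duplicate tip labels in tip data")
  if (any(!is.na(state) & !(state %in% 0:1))) stop("state must be 0, 1 or NA")
  if (any(is.na(richness)) || any(richness < 1L)) stop("richness must be >= 1")
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("sampling fraction f must be in (0, 1]")
  out <- data.frame(tip_label = as.character(tip_label), state = state,
                    richness = richness, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "f") <- f
  class(out) <- c("tip_data", "data.frame")
  out
}

#' Read a tip table from TSV
#'
#' Expects columns `tip_label`, `state` (0/1/NA) and optionally `richness`
#' (default 1).
#'
#' @param path TSV file path.
#' @inheritParams tip_data
#' @return a `tip_data` object.
#' @export
read_tip_data <- function(path, mode = c("proportional", "unresolved"), f = 1) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tip_label", "state") %in% names(df)))
    stop("tip table must have columns tip_label, state")
  if (is.null(df$richness)) df$richness <- 1L
  tip_data(df$tip_label, df$state, df$richness, mode = match.arg(mode), f = f)
}

#' Write a tip table to TSV
#' @param tips a `tip_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tip_data <- function(tips, path) {
  write.table(as.data.frame(tips), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# align a tip_data table to the tip order of a tree, erroring on mismatch
match_tips <- function(tips, phy) {
  i <- match(phy$tip.label, tips$tip_label)
  if (anyNA(i))
    stop("tip data missing for: ",
         paste(head(phy$tip.label[is.na(i)], 5), collapse = ", "))
  out <- tips[i, , drop = FALSE]
  attributes(out)[c("mode", "f")] <- attributes(tips)[c("mode", "f")]
  class(out) <- class(tips)
  rownames(out) <- NULL
  out
}

#' Lineage-through-time curve
#'
#' Returns the step curve of reconstructed lineage counts against age, from
#' the root to the present, as `(age, lineages)` pairs: one row per
#' branching event giving the count immediately rootward of that age, plus a
#' final row at age 0 with the tip count.  With `tips` and `state` given,
#' only branches with at least one descendant tip in that state are counted
#' (state-filtered curves, e.g. a C4-only accumulation curve).
#'
#' @param phy an ultrametric `phylo` object.
#' @param tips optional [tip_data()] table (needed for state filtering).
#' @param state optional state (0 or 1) to filter on.
#' @param tol_ultra passed to [as_timetree()].
#' @return a `data.frame` with columns `age`, `lineages`.
#' @export
ltt_curve <- function(phy, tips = NULL, state = NULL, tol_ultra = NULL) {
  phy <- as_timetree(phy, tol_ultra = tol_ultra)
  ntip <- ape::Ntip(phy)
  age <- node_ages(phy)
  if (is.null(state)) {
    keep_edge <- rep(TRUE, nrow(phy$edge))
    n_final <- ntip
  } else {
    if (is.null(tips)) stop("state filtering requires a tip_data table")
    tips <- match_tips(tips, phy)
    has <- logical(ntip + phy$Nnode)
    has[seq_len(ntip)] <- !is.na(tips$state) & tips$state == state
    po <- ape::reorder.phylo(phy, "postorder")
    for (k in seq_len(nrow(po$edge)))
      has[po$edge[k, 1]] <- has[po$edge[k, 1]] || has[po$edge[k, 2]]
    keep_edge <- has[phy$edge[, 2]]
    n_final <- sum(has[seq_len(ntip)])
    if (n_final == 0L) stop("no tips in the requested state")
  }
  t_old <- age[phy$edge[, 1]][keep_edge]
  t_young <- age[phy$edge[, 2]][keep_edge]
  ev <- sort(unique(t_old), decreasing = TRUE)
  ## lineage count in the interval immediately below each event age
  below <- vapply(ev, function(a) sum(t_old >= a & t_young < a), integer(1))
  ## count reported at an event age is the count immediately rootward of it;
  ## rootward of the oldest event there is the single root (or clade stem)
  above <- c(max(1L, sum(t_old > ev[1] & t_young <= ev[1])),
             below[-length(below)])
  data.frame(age = c(ev, 0), lineages = c(above, n_final))
}

#' MRCA, clade ages and induced subtree for a set of tips
#'
#' @param phy a `phylo` object.
#' @param labels character vector of tip labels (length >= 2).
#' @return a list with `mrca` (node number), `crown_age`, `stem_age` (`NA`
#'   with `is_root = TRUE` when the MRCA is the root), and `subtree` (the
#'   clade as a `phylo` object).
#' @export
mrca_and_clade <- function(phy, labels) {
  miss <- setdiff(labels, phy$tip.label)
  if (length(miss)) stop("unknown tip label(s): ", paste(miss, collapse = ", "))
  if (length(labels) < 2L) stop("need at least two tips")
  node <- ape::getMRCA(phy, labels)
  age <- node_ages(phy)
  is_root <- node == ape::Ntip(phy) + 1L
  stem <- if (is_root) NA_real_ else age[phy$edge[phy$edge[, 2] == node, 1]]
  list(mrca = node, crown_age = age[node], stem_age = stem, is_root = is_root,
       subtree = ape::extract.clade(phy, node))
}
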