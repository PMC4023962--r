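test_that("scale_to_root_age rescales, is identity at the same age, and composes", {
  set.seed(21)
  tr <- as_timetree(ape::rcoal(10))
  doubled <- scale_to_root_age(tr, 2 * root_age(tr))
  expect_equal(doubled$edge.length, 2 * tr$edge.length)
  same <- scale_to_root_age(tr, root_age(tr))
  expect_equal(same$edge.length, tr$edge.length)
  tr50 <- as_timetree(ape::rcoal(50))
  ab <- scale_to_root_age(scale_to_root_age(tr50, 7), 13)
  ac <- scale_to_root_age(tr50, 13)
  expect_equal(ab$edge.length, ac$edge.length, tolerance = 1e-12)
  ## age ratios preserved
  expect_equal(node_ages(ab) / root_age(ab),
               node_ages(tr50) / root_age(tr50), tolerance = 1e-12)
  expect_error(scale_to_root_age(tr, 0), "> 0")
})

test_that("grafting replaces the placeholder cherry at the right ages", {
  bb <- ape::read.tree(text = "((P1:2,P2:2):3,Out:5);")
  sub <- as_timetree(ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:1.5):0.5);"))
  out <- graft(bb, c("P1", "P2"), sub, target_crown_age = 2)
  expect_equal(ape::Ntip(out), 3 - 2 + 4)
  expect_equal(root_age(out), 5)
  expect_true(ape::is.ultrametric(out, tol = 1e-8))
  m <- mrca_and_clade(out, c("a", "d"))
  expect_equal(m$crown_age, 2, tolerance = 1e-10)
  expect_equal(m$stem_age, 5, tolerance = 1e-10)  # placeholder stem kept
  ## outside node ages untouched
  expect_equal(node_ages(out)[match("Out", out$tip.label)], 0)
  expect_error(graft(bb, c("P1", "Out"), sub, 2), "monophyletic")
  expect_error(graft(bb, c("P1", "P2"), sub, 7), "below the stem age")
})

test_that("grafting the placeholder cherry itself is the identity", {
  bb <- ape::read.tree(text = "(((P1:2,P2:2):3,X:5):2,Out:7);")
  sub <- ape::read.tree(text = "(P1:2,P2:2);")
  out <- graft(bb, c("P1", "P2"), sub, target_crown_age = 2)
  expect_true(ape::all.equal.phylo(out, bb, use.edge.length = TRUE))
})

test_that("sequential grafts conserve the tip-count formula", {
  set.seed(8)
  bb <- as_timetree(ape::rcoal(12))
  bb$edge.length <- bb$edge.length * (40 / root_age(bb))
  n_expect <- ape::Ntip(bb)
  for (k in 1:6) {
    pair <- NULL
    ## find a cherry to use as placeholder pair
    for (v in (ape::Ntip(bb) + 1):(ape::Ntip(bb) + bb$Nnode)) {
      kids <- bb$edge[bb$edge[, 1] == v, 2]
      if (all(kids <= ape::Ntip(bb))) { pair <- bb$tip.label[kids]; break }
    }
    stem <- mrca_and_clade(bb, pair)$stem_age
    m <- sample(3:6, 1)
    sub <- as_timetree(ape::rcoal(m))
    sub$tip.label <- sprintf("g%d_%s", k, sub$tip.label)
    bb <- graft(bb, pair, sub, target_crown_age = 0.5 * stem)
    n_expect <- n_expect - 2 + m
    expect_equal(ape::Ntip(bb), n_expect)
    expect_true(ape::is.ultrametric(bb, tol = 1e-8))
  }
})

test_that("largest-remainder division matches the Poa example", {
  expect_equal(largest_remainder(550, 3), c(184L, 183L, 183L))
  expect_equal(sum(largest_remainder(550, 3)), 550)
  expect_equal(largest_remainder(10, 1), 10L)
  for (i in 1:20) {
    tot <- sample(1:1000, 1); k <- sample(1:7, 1)
    sh <- largest_remainder(tot, k)
    expect_equal(sum(sh), tot)
    expect_lte(diff(range(sh)), 1L)
  }
})

test_that("genus collapse applies the splitting, spreading and block rules", {
  tr <- ape::read.tree(text = paste0(
    "(((Poa_a:1,Poa_b:1):1,(Poa_c:1,Poa_d:1):1):3,",
    "(Briza_x:2,(Pan_a:1,Pan_b:1):1):3);"))
  td <- tip_data(tr$tip.label, c(0, 0, 0, 0, 0, 1, 1), mode = "proportional")
  rt <- data.frame(genus = c("Poa", "Briza", "Pan"), size = c(550, 10, 100))
  col <- collapse_to_representatives(tr, td, rt, split_threshold = 190,
                                     spread_genera = "Pan")
  expect_equal(sum(col$tips$richness), 550 + 10 + 100)
  poa <- col$blocks[col$blocks$genus == "Poa", ]
  expect_equal(sort(poa$richness, decreasing = TRUE), c(184, 183, 183))
  expect_equal(col$blocks$richness[col$blocks$genus == "Briza"], 10)
  ## Pan spread equally over its 2 tips then collapsed into one pure block
  pan <- col$blocks[col$blocks$genus == "Pan", ]
  expect_equal(sum(pan$richness), 100)
  expect_error(
    collapse_to_representatives(tr, td, rt[-1, ], split_threshold = 190),
    "missing genus")
})

test_that("mixed-state genera split into state-pure monophyletic blocks", {
  tr <- ape::read.tree(text =
    "(((Gx_a:1,Gx_b:1):1,Gx_c:2):2,(Hy_a:1.5,Hy_b:1.5):2.5);")
  td <- tip_data(tr$tip.label, c(0, 0, 1, 0, 0), mode = "proportional")
  rt <- data.frame(genus = c("Gx", "Hy"), size = c(30, 5),
                   size_c3 = c(20, 5), size_c4 = c(10, 0))
  col <- collapse_to_representatives(tr, td, rt)
  gx <- col$blocks[col$blocks$genus == "Gx", ]
  expect_equal(nrow(gx), 2L)
  expect_setequal(gx$state, c(0L, 1L))
  expect_equal(gx$richness[gx$state == 0], 20)
  expect_equal(gx$richness[gx$state == 1], 10)
  expect_equal(sum(col$tips$richness), 35)
})

test_that("assignment report tallies richness, coverage and implied f", {
  td <- tip_data(letters[1:5], 0, richness = c(10, 5, 1, 3, 1),
                 mode = "unresolved", f = 1)
  rep <- validate_assignment(td, known_total = 25)
  expect_equal(rep$assigned, 20)
  expect_equal(rep$coverage, 0.8)
  expect_equal(rep$f_implied, 5 / 20)
  td1 <- tip_data(letters[1:4], 0, richness = 1, mode = "proportional")
  rep1 <- validate_assignment(td1)
  expect_equal(rep1$assigned, 4)
  expect_equal(rep1$f_implied, 1)
})
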