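test_that("newick chronograms read with correct tip ages and root age", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(newick_3tip, f)
  tr <- read_time_tree(f, "newick")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(unname(tip_ages(tr)), c(0, 0, 0))
  expect_equal(root_age(tr), 2)

  writeLines(newick_fossil, f)
  tr <- read_time_tree(f, "newick")
  ages <- tip_ages(tr)
  expect_equal(unname(ages[c("A", "C")]), c(0, 0))
  expect_equal(unname(ages["B"]), 0.5)
  expect_equal(unname(is_fossil_tip(tr)), c(FALSE, TRUE, FALSE))
})

test_that("tip age equals root age minus root-to-tip path length", {
  sc <- scenario_spec(n_extant = 15, fossil_fraction = 0.3, seed = 5)
  tr <- simulate_tree(sc)
  depth <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  expect_equal(unname(tip_ages(tr)), root_age(tr) - depth, tolerance = 1e-6)
})

test_that("degenerate internal edges collapse to polytomies; pendant edges survive", {
  # internal 1e-12 edge collapses
  tr <- read_newick_text("(((A:1,B:1):1e-12,C:1):1,D:2);")
  expect_equal(tr$Nnode, 2L)
  expect_equal(ape::Ntip(tr), 4L)
  # pendant 1e-12 edge is retained even though it is below the threshold
  tr2 <- read_newick_text("((A:1,B:1e-12):1,C:2);")
  expect_equal(ape::Ntip(tr2), 3L)
  expect_true("B" %in% tr2$tip.label)
  expect_equal(tr2$Nnode, 2L)
})

test_that("malformed trees are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C);", f) # missing a branch length
  expect_error(read_time_tree(f), "branch length|duration|chronogram")
  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_time_tree(f), "duplicate")
  writeLines("(A:1,B:1,C:2);", f) # basal trichotomy: unrooted in newick
  expect_error(read_time_tree(f), "unrooted|root")
})

test_that("newick and nexus round-trips preserve topology, durations, labels", {
  sc <- scenario_spec(n_extant = 12, fossil_fraction = 0.2, seed = 3)
  tr <- simulate_tree(sc)
  for (fmt in c("newick", "nexus")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_time_tree(tr, f, fmt)
    tr2 <- read_time_tree(f, fmt)
    expect_setequal(tr2$tip.label, tr$tip.label)
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)]
    expect_equal(d2, d1, tolerance = 1e-9)
  }
})

test_that("pruning fossil tips conserves extant root-to-tip distances", {
  tr <- read_newick_text("((A:1,B:0.5):1,(C:1,D:1):1);") # B is the fossil
  pr <- prune_fossil_tips(tr)
  expect_equal(ape::Ntip(pr), 3L)
  ext <- c("A", "C", "D")
  d1 <- ape::cophenetic.phylo(tr)[ext, ext]
  d2 <- ape::cophenetic.phylo(pr)[ext, ext]
  expect_equal(d2, d1, tolerance = 1e-9)

  sc <- scenario_spec(n_extant = 20, fossil_fraction = 0.25, seed = 11)
  big <- simulate_tree(sc)
  prb <- prune_fossil_tips(big)
  expect_equal(ape::Ntip(prb), 20L)
  expect_true(ape::is.ultrametric(prb, tol = 1e-8))
  ext <- prb$tip.label
  expect_equal(ape::cophenetic.phylo(prb)[ext, ext],
               ape::cophenetic.phylo(big)[ext, ext], tolerance = 1e-9)
})

test_that("pruning a fossil-free tree is the identity; tiny trees refuse", {
  tr <- read_newick_text(newick_3tip)
  expect_identical(prune_fossil_tips(tr), tr)
  trf <- read_newick_text(newick_fossil) # pruning would leave 2 tips
  expect_error(prune_fossil_tips(trf), "at least 3")
})

test_that("outgroup grafting follows the separation geometry on both readings", {
  tr <- read_newick_text(newick_3tip)
  tt <- traits_for(tr, c(0, 0, 0))
  g <- graft_outgroup(tr, tt, outgroup_mass = 0.5)
  expect_equal(ape::Ntip(g$tree), 4L)
  # total separation reading: stem 4.99 + pendant 0.01
  expect_equal(root_age(g$tree), root_age(tr) + 4.99)
  ages <- tip_ages(g$tree)
  expect_equal(unname(ages["pseudo_outgroup"]), root_age(g$tree) - 0.01)
  # original pairwise distances unchanged
  d0 <- ape::cophenetic.phylo(tr)
  d1 <- ape::cophenetic.phylo(g$tree)[rownames(d0), colnames(d0)]
  expect_equal(d1, d0, tolerance = 1e-12)
  # trait record added with the requested mass
  expect_equal(g$traits$mass_kg[g$traits$species == "pseudo_outgroup"], 0.5)
  # stem reading: the stem edge itself is 5 Myr
  g2 <- graft_outgroup(tr, tt, 0.5, mode = "stem")
  expect_equal(root_age(g2$tree), root_age(tr) + 5)
})

test_that("grafting then pruning the outgroup recovers the original tree", {
  sc <- scenario_spec(n_extant = 10, seed = 2)
  tr <- simulate_tree(sc)
  tt <- traits_for(tr, rnorm(10))
  for (m in c(0.1, 0.5, 1, 5, 10, 20)) {
    g <- graft_outgroup(tr, tt, m)
    back <- ape::drop.tip(g$tree, "pseudo_outgroup")
    expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-9)
  }
  expect_error(graft_outgroup(tr, tt, -1), "positive")
  expect_error(graft_outgroup(tr, tt, 1, separation = 0.005), "exceed")
})

test_that("trait tables parse, log-transform and validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,mass_kg", "Afrotheria_anc,0.1", "Big_sp,1500"), f)
  tt <- read_traits(f)
  expect_equal(tt$logmass[tt$species == "Afrotheria_anc"], -1)
  expect_equal(back_transform(-1), 0.1)
  # tab-separated, no header
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t0.25", "B\t4"), f2)
  tt2 <- read_traits(f2)
  expect_equal(tt2$logmass, log10(c(0.25, 4)))
  # errors carry the offending row
  writeLines(c("species,mass_kg", "A,2", "B,-5"), f)
  expect_error(read_traits(f), "row 2")
  expect_error(trait_table(c(A = 1, A = 2)), "duplicate")
})

test_that("binding traits to a tree demands complete coverage, allows extras", {
  tr <- read_newick_text(newick_3tip)
  tt <- trait_table(c(A = 1, B = 2, C = 3, D = 4))
  x <- bind_traits(tr, tt)
  expect_equal(unname(x), log10(c(1, 2, 3)))
  expect_error(bind_traits(tr, trait_table(c(A = 1, B = 2))), "C")
})
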