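test_that("pruning a fully extant tree is the identity", {
  s <- simulateTree(pureBirthParams(20, seed = 3L))
  pr <- pruneToExtant(s)
  expect_identical(ape::write.tree(asPhylo(pr)), ape::write.tree(asPhylo(s)))
  expect_identical(tipStates(pr), tipStates(s))
})

test_that("pruning a cherry with one extinct tip leaves one full-depth lineage", {
  pr <- pruneToExtant(cherrySim())
  phy <- asPhylo(pr)
  expect_equal(phy$tip.label, "tA")
  expect_equal(sum(phy$edge.length), 2.5)   # root-to-tip path preserved
  expect_equal(unname(tipStates(pr)), 0L)
})

test_that("pruning preserves extant tip depths and pairwise path lengths", {
  p <- diversificationParams(stopValue = 150, seed = 21L)
  s <- simulateTree(p)
  expect_gt(sum(!tipExtant(s)), 0L)         # extinction actually happened
  pr <- pruneToExtant(s)
  expect_true(all(tipExtant(pr)))
  expect_equal(sort(names(tipStates(pr))), sort(names(which(tipExtant(s)))))
  ## brute-force pairwise path lengths among extant tips, before vs after
  keep <- names(which(tipExtant(s)))
  d0 <- ape::cophenetic.phylo(asPhylo(s))[keep, keep]
  d1 <- ape::cophenetic.phylo(asPhylo(pr))[keep, keep]
  expect_lt(max(abs(d0 - d1)), 1e-9 * totalTime(s))
  ## extant tip depths (from the origin) all equal totalTime
  dep <- ape::node.depth.edgelength(asPhylo(pr))[seq_along(keep)] +
    asPhylo(pr)$root.edge
  expect_equal(dep, rep(totalTime(s), length(keep)), tolerance = 1e-9)
})

test_that("richness by state counts tips and conserves the total", {
  expect_equal(richnessByState(c(0, 0, 1, 2), K = 3), c(2L, 1L, 1L))
  expect_equal(richnessByState(rep(0L, 7), K = 4), c(7L, 0L, 0L, 0L))
  expect_error(richnessByState(c(0, 3), K = 3), "out of range")
  s <- pruneToExtant(simulateTree(diversificationParams(stopValue = 80,
                                                        seed = 4L)))
  expect_equal(sum(richnessByState(s)), 80L)
})

test_that("relationship classification follows the documented rule", {
  expect_equal(classifyRelationship(c(1, 2, 4, 8, 16)), "positive")
  expect_equal(classifyRelationship(c(16, 8, 4, 2, 1)), "negative")
  expect_equal(classifyRelationship(c(2, 8, 3, 1, 1)), "hump")
  ## interior max but endpoints too high for a hump call -> monotone rho path
  expect_equal(classifyRelationship(c(9, 10, 9)), "flat")
  expect_equal(classifyRelationship(c(5, 5, 5)), "flat")
  expect_error(classifyRelationship(c(0, 0, 0)), "undefined")
  expect_error(classifyRelationship(c(1, 2)), "at least 3")
  ## invariance to positive rescaling
  set.seed(1)
  for (i in 1:20) {
    v <- rpois(6, 5) + 1
    expect_identical(classifyRelationship(v),
                     classifyRelationship(v * runif(1, 0.1, 90)))
  }
})

test_that("subclade extraction matches a brute-force scan", {
  s <- pruneToExtant(simulateTree(diversificationParams(stopValue = 120,
                                                        seed = 9L)))
  cl <- extractSubclades(s, c(0.25, 0.6), minSize = 5L)
  phy <- asPhylo(s)
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  crown <- max(depth[seq_len(ntip)])
  ## independent scan over internal nodes with ape's clade extraction
  expected <- integer(0)
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    age <- crown - depth[v]
    size <- length(ape::extract.clade(phy, v)$tip.label)
    if (age >= 0.25 * crown && age <= 0.6 * crown && size >= 5L)
      expected <- c(expected, v)
  }
  ## tips cannot qualify here (age 0 < 0.25 * crown), so compare directly
  expect_setequal(cl$cladeId, expected)
  ## every reported clade satisfies both filters, and richness sums to size
  expect_true(all(cl$age >= 0.25 * crown - 1e-9 &
                  cl$age <= 0.6 * crown + 1e-9))
  expect_true(all(cl$size >= 5L))
  rs <- as.matrix(cl[, grep("^richness_s", names(cl))])
  expect_equal(unname(rowSums(rs)), as.numeric(cl$size))
})

test_that("degenerate windows and sizes behave as specified", {
  s <- pruneToExtant(simulateTree(pureBirthParams(30, seed = 12L)))
  ## the root is the only clade of full root age
  cl <- extractSubclades(s, c(1, 1), minSize = 1L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 30)
  ## impossible size filter yields an empty table
  expect_equal(nrow(extractSubclades(s, c(0, 1), minSize = 31L)), 0L)
  expect_error(extractSubclades(s, c(0.5, 0.2), 1L), "ageWindow")
  expect_error(extractSubclades(s, c(-0.1, 0.5), 1L), "ageWindow")
})

test_that("non-nested selection drops clades under a selected ancestor", {
  s <- pruneToExtant(simulateTree(diversificationParams(stopValue = 150,
                                                        seed = 30L)))
  all_cl <- extractSubclades(s, c(0.1, 0.9), minSize = 3L)
  top_cl <- extractSubclades(s, c(0.1, 0.9), minSize = 3L, nonNested = TRUE)
  expect_lte(nrow(top_cl), nrow(all_cl))
  ## no selected clade may contain another selected clade's tips
  phy <- asPhylo(s)
  tipsOf <- lapply(top_cl$cladeId, function(v)
    ape::extract.clade(phy, v)$tip.label)
  for (i in seq_along(tipsOf)) {
    for (j in seq_along(tipsOf)) {
      if (i != j) expect_false(all(tipsOf[[j]] %in% tipsOf[[i]]))
    }
  }
})

test_that("Newick round trip preserves topology, lengths and states", {
  s <- simulateTree(diversificationParams(stopValue = 60, seed = 8L))
  tf <- withr::local_tempfile(fileext = ".nwk")
  sf <- withr::local_tempfile(fileext = ".tsv")
  writePhyloSim(s, tf, sf)
  rd <- readPhyloSim(tf, sf, nStates = 8L)
  pr <- pruneToExtant(s)
  expect_true(ape::all.equal.phylo(asPhylo(rd), asPhylo(pr),
                                   use.edge.length = FALSE))
  d0 <- ape::cophenetic.phylo(asPhylo(pr))
  d1 <- ape::cophenetic.phylo(asPhylo(rd))[rownames(d0), colnames(d0)]
  expect_lt(max(abs(d0 - d1)), 1e-9 * totalTime(s))
  expect_equal(tipStates(rd)[names(tipStates(pr))], tipStates(pr))
  expect_equal(totalTime(rd), totalTime(pr), tolerance = 1e-9)
})

test_that("annotated Newick carries a state comment behind every tip", {
  s <- simulateTree(diversificationParams(stopValue = 25, seed = 14L))
  tf <- withr::local_tempfile(fileext = ".nwk")
  sf <- withr::local_tempfile(fileext = ".tsv")
  writePhyloSim(s, tf, sf, annotated = TRUE)
  nwk <- readLines(tf)
  pr <- pruneToExtant(s)
  expect_equal(lengths(regmatches(nwk, gregexpr("\\[&state=", nwk))),
               sum(tipExtant(s)))
  for (lb in sample(names(tipStates(pr)), 5)) {
    expect_match(nwk, sprintf("%s\\[&state=%d\\]:", lb, tipStates(pr)[[lb]]))
  }
})
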