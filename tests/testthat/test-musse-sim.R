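test_that("speciation rate ramps linearly over the state space", {
  p <- diversificationParams(nStates = 5L, lambdaMin = 0.18, lambdaMax = 0.26)
  expect_equal(stateSpeciationRate(0L, p), 0.18)
  expect_equal(stateSpeciationRate(4L, p), 0.26)
  expect_equal(stateSpeciationRate(2L, p), 0.22)
  rates <- stateSpeciationRate(0:4, p)
  expect_true(all(diff(rates) >= 0))
  ## K = 1 collapses to lambdaMin
  p1 <- diversificationParams(nStates = 1L, lambdaMin = 0.2,
                              lambdaMax = 0.2, q = 0, rootState = 0L)
  expect_equal(stateSpeciationRate(0L, p1), 0.2)
  expect_error(stateSpeciationRate(5L, p), "out of range")
  expect_error(stateSpeciationRate(-1L, p), "out of range")
})

test_that("parameter invariants are enforced", {
  expect_error(diversificationParams(mu = -0.1), "rates")
  expect_error(diversificationParams(lambdaMin = 0.3, lambdaMax = 0.2),
               "lambdaMin")
  expect_error(diversificationParams(rootState = 8L), "rootState")
  expect_error(diversificationParams(stopValue = -1), "stopValue")
  expect_error(diversificationParams(stopRule = "bogus"))
})

test_that("pure-birth run stops at exactly the target extant count", {
  s <- simulateTree(pureBirthParams(4, seed = 7L))
  expect_equal(sum(tipExtant(s)), 4L)
  expect_equal(asPhylo(s)$Nnode, 3L)
  expect_equal(length(asPhylo(s)$tip.label), 4L)
})

test_that("the same seed reproduces the tree bit for bit", {
  p <- diversificationParams(stopValue = 200, seed = 42L)
  s1 <- simulateTree(p)
  s2 <- simulateTree(p)
  expect_identical(ape::write.tree(asPhylo(s1)), ape::write.tree(asPhylo(s2)))
  expect_identical(tipStates(s1), tipStates(s2))
  expect_identical(tipExtant(s1), tipExtant(s2))
  ## a different seed gives a different tree
  s3 <- simulateTree(diversificationParams(stopValue = 200, seed = 43L))
  expect_false(identical(ape::write.tree(asPhylo(s1)),
                         ape::write.tree(asPhylo(s3))))
})

test_that("extant-count stopping and ultrametricity hold across parameter draws", {
  set.seed(99)
  for (i in 1:5) {
    K <- sample(2:8, 1L)
    p <- diversificationParams(
      nStates = K, lambdaMin = runif(1, 0.1, 0.2),
      lambdaMax = runif(1, 0.2, 0.3), mu = runif(1, 0, 0.1),
      q = runif(1, 0.02, 0.3), rootState = sample.int(K, 1L) - 1L,
      stopValue = sample(20:200, 1L), seed = i)
    s <- simulateTree(p)
    expect_equal(sum(tipExtant(s)), as.integer(p@stopValue))
    expect_true(validObject(s))       # includes the ultrametricity check
    expect_true(all(tipStates(s) >= 0 & tipStates(s) < K))
  }
})

test_that("mean extant count under pure birth matches the e^(lambda t) oracle", {
  ## analytic oracle for a Yule process observed at time t
  lambda <- 0.2; t <- 10
  counts <- vapply(1:300, function(i) {
    sum(tipExtant(simulateTree(pureBirthParams(t, seed = i,
                                               rule = "max_time"))))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - exp(lambda * t)), 3 * se)
})

test_that("tip states are symmetric under a neutral, symmetric model", {
  ## constant speciation, no extinction, symmetric transitions, middle root:
  ## mirrored state counts must agree in expectation. Tips within a tree are
  ## correlated through shared ancestry, so the test operates on independent
  ## per-tree mirrored-count differences, not on pooled tip counts.
  K <- 5L
  d1 <- d2 <- numeric(200)
  for (i in 1:200) {
    p <- diversificationParams(
      nStates = K, lambdaMin = 0.3, lambdaMax = 0.3, mu = 0, q = 0.1,
      rootState = 2L, stopValue = 64, seed = 1000L + i)
    rb <- richnessByState(simulateTree(p))
    d1[i] <- rb[1] - rb[5]
    d2[i] <- rb[2] - rb[4]
  }
  expect_gt(stats::t.test(d1)$p.value, 0.01)
  expect_gt(stats::t.test(d2)$p.value, 0.01)
})

test_that("whole-tree extinction triggers restarts and eventually errors", {
  ## extinction-dominated process: every attempt dies
  p <- diversificationParams(nStates = 1L, lambdaMin = 0.01,
                             lambdaMax = 0.01, mu = 5, q = 0, rootState = 0L,
                             stopValue = 100, seed = 1L, maxRestarts = 3L)
  err <- tryCatch(simulateTree(p), error = identity)
  expect_s3_class(err, "phylocov_sim_failure")
  expect_equal(err$restarts, 3L)
  ## moderate extinction: survives via restarts, count reported
  p2 <- diversificationParams(stopValue = 50, seed = 5L)
  s2 <- simulateTree(p2)
  expect_gte(s2@restarts, 0L)
})

test_that("per-neighbor and total transition semantics agree when K = 2", {
  ## with a single neighbor the two interpretations coincide
  args <- list(nStates = 2L, lambdaMin = 0.2, lambdaMax = 0.25, mu = 0.05,
               q = 0.1, rootState = 0L, stopValue = 100, seed = 17L)
  s1 <- simulateTree(do.call(diversificationParams,
                             c(args, qMode = "per_neighbor")))
  s2 <- simulateTree(do.call(diversificationParams, c(args, qMode = "total")))
  expect_identical(ape::write.tree(asPhylo(s1)), ape::write.tree(asPhylo(s2)))
  expect_identical(tipStates(s1), tipStates(s2))
})

test_that("max_time runs stop at the horizon with extant tips at full depth", {
  p <- diversificationParams(stopRule = "max_time", stopValue = 15,
                             seed = 2L)
  s <- simulateTree(p)
  expect_equal(totalTime(s), 15)
  expect_true(validObject(s))
})
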