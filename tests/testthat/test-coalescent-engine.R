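test_that("pairwise coalescence times match the single-deme expectation", {
  set.seed(43)
  mod <- getModel("A")
  ## one deme of 1000 gene copies: E[T2] = 1000 generations
  req <- simulationRequest(100, c(2L, 0L, 0L), "mitochondrial", 1e-8)
  par <- c(N_C = 1000, N_P = 10, N_A = 10, T_CP = 1e12, T_A = 1e13)
  t2 <- replicate(3000, max(simulateGenealogy(mod, par, req)@nodeTime))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1000), 3 * se)
})

test_that("total branch length matches the coalescent closed form", {
  set.seed(47)
  mod <- getModel("A")
  req <- simulationRequest(100, c(10L, 0L, 0L), "mitochondrial", 1e-8)
  par <- singleDemeParams(N = 2000)
  tl <- replicate(3000, totalBranchLength(
    simulateGenealogy(mod, par, req)))
  expected <- 2 * 2000 * sum(1 / (1:9))
  se <- sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - expected), 3 * se)
})

test_that("lineages in separate demes cannot coalesce before the split", {
  set.seed(53)
  mod <- getModel("A")
  req <- simulationRequest(100, c(1L, 1L, 0L), "mitochondrial", 1e-8)
  par <- c(N_C = 100, N_P = 100, N_A = 100, T_CP = 5e4, T_A = 1e6)
  tm <- replicate(500, max(simulateGenealogy(mod, par, req)@nodeTime))
  expect_true(all(tm >= 5e4))
})

test_that("genealogies convert to valid ultrametric ape trees", {
  set.seed(59)
  g <- simulateGenealogy(getModel("A"), singleDemeParams(),
                         singleDemeRequest(8, 5))
  tr <- asPhylo(g)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 8)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(max(abs(depths[1:8] - max(g@nodeTime))), 0, tolerance = 1e-9)
})

test_that("mutation counts follow the Poisson expectation on a fixed tree", {
  set.seed(61)
  g <- simulateGenealogy(getModel("A"), singleDemeParams(N = 5000),
                         singleDemeRequest(6, 5))
  L <- 2000; mu <- 2e-7
  expected <- totalBranchLength(g) * mu * L
  s <- replicate(4000, segregatingSites(
    sequences(dropMutations(g, L, mu))))
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - expected), 3 * se)

  ## mu = 0: monomorphic
  aln0 <- dropMutations(g, 100, 0)
  expect_equal(segregatingSites(sequences(aln0)), 0)
})

test_that("a single external-branch mutation yields a singleton site", {
  set.seed(67)
  found <- FALSE
  for (r in 1:200) {
    g <- simulateGenealogy(getModel("A"), singleDemeParams(),
                           singleDemeRequest(5, 1))
    aln <- dropMutations(g, 1000, 1 / (2 * 1e4) / 1000)
    m <- alignmentMatrix(aln)
    derived <- colSums(m == "T")
    if (sum(derived > 0) == 1 && all(derived[derived > 0] == 1)) {
      ## one singleton among n=5: the 4 pairs involving the carrier each
      ## differ at 1 site, so the mean over the 10 pairs is 4/10
      expect_equal(meanPairwiseDifferences(m), 4 / 10)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("simulated statistic vectors share the observed definition", {
  ## the compiled per-site tally must agree with the character-based route
  ## computed on the very alignments the genealogies imply; check via the
  ## pseudo-observed generator (one sequence per sampled copy, no missing)
  set.seed(71)
  pd <- generatePseudoObserved(easyPreset("G"))
  obsChar <- observedStatVector(pd$dataset, "nuclear")
  expect_equal(names(obsChar), statNames())

  ## and directly: statistic order and names from the simulator
  req <- easyNuclearRequest()
  v <- simulateStatVector(getModel("G"), midPriorParameters(getModel("G")),
                          req)
  expect_equal(names(v), statNames())
  expect_true(all(is.finite(v)))
})

test_that("gene flow depresses differentiation relative to isolation", {
  set.seed(73)
  req <- easyNuclearRequest()
  par <- c(N_C = 2e4, N_P = 2e4, N_A = 2e4, T_CP = 5e5, T_A = 4e6)
  e <- getModel("E"); a <- getModel("A")
  pe <- c(par, m_CP = 1e-4, m_CA = 1e-4, m_PA = 1e-4)
  fstE <- replicate(200, simulateStatVector(e, pe, req)["fst_CP"])
  fstA <- replicate(200, simulateStatVector(a, par, req)["fst_CP"])
  expect_lt(mean(fstE) + 0.1, mean(fstA))
})

test_that("identical seeds give bit-identical statistic vectors", {
  req <- easyNuclearRequest()
  par <- midPriorParameters(getModel("G"))
  set.seed(101); v1 <- simulateStatVector(getModel("G"), par, req)
  set.seed(101); v2 <- simulateStatVector(getModel("G"), par, req)
  expect_identical(v1, v2)
  set.seed(101)
  t1 <- buildReferenceTable(getModel("D"), req, 200)
  set.seed(101)
  t2 <- buildReferenceTable(getModel("D"), req, 200)
  expect_identical(t1@stats, t2@stats)
  expect_identical(t1@params, t2@params)
})

test_that("expected S and pi match Watterson/Tajima in the one-deme limit", {
  set.seed(79)
  mod <- getModel("A")
  req <- singleDemeRequest(10, thetaLocus = 5)
  par <- singleDemeParams()
  vs <- replicate(5000, simulateStatVector(mod, par, req)[c("S_chilensis",
                                                            "pi_chilensis")])
  S <- vs[1, ]; pi <- vs[2, ]
  expect_lt(abs(mean(S) - 5 * sum(1 / (1:9))), 3 * sd(S) / sqrt(length(S)))
  expect_lt(abs(mean(pi) - 5), 3 * sd(pi) / sqrt(length(pi)))
})
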