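# A ReferenceTable with externally supplied statistics, for controlled tests
toyTable <- function(params, stats, model = getModel("A"),
                     priors = defaultPriors("nuclear")) {
  colnames(stats) <- statNames()[seq_len(ncol(stats))]
  req <- simulationRequest(100, c(2L, 2L, 2L), "autosomal", 1e-9)
  new("ReferenceTable", model = model, params = params, stats = stats,
      priors = priors, request = req)
}

test_that("distances are MAD-normalized Euclidean with documented fallbacks", {
  ## hand-computed 3-row, 2-statistic example
  tab <- matrix(c(1, 2, 3,
                  10, 20, 30), ncol = 2)
  obs <- c(2, 20)
  sc <- c(mad(c(1, 2, 3)), mad(c(10, 20, 30)))
  byHand <- sqrt(((tab[, 1] - 2) / sc[1])^2 + ((tab[, 2] - 20) / sc[2])^2)
  expect_equal(statDistances(obs, tab), byHand)
  ## a row equal to the observation is at distance 0
  expect_equal(statDistances(c(1, 10), tab)[1], 0)
  ## rescaling one statistic leaves the ranking unchanged
  tab2 <- tab; tab2[, 2] <- tab2[, 2] * 1000
  expect_equal(order(statDistances(c(2, 20000), tab2)),
               order(statDistances(obs, tab)))
  ## constant statistic dropped with a warning
  tab3 <- cbind(tab, 5)
  expect_warning(d3 <- statDistances(c(2, 20, 5), tab3), "zero spread")
  expect_equal(d3, statDistances(obs, tab))
  expect_error(statDistances(c(1, 2, 3), tab), "dimension mismatch")
})

test_that("rejection keeps the tolerance fraction with Epanechnikov weights", {
  set.seed(83)
  d <- runif(10000)
  rs <- rejectionSample(d, 0.01)
  expect_length(rs$index, 100)
  expect_equal(rs$radius, max(d[rs$index]))
  expect_equal(rs$weights, 1 - (rs$distances / rs$radius)^2)
  ## tolerance 1 keeps everything
  expect_length(rejectionSample(d, 1)$index, 10000)
  ## deterministic tie-breaking by row index
  dt <- c(0.5, 0.2, 0.5, 0.1)
  expect_equal(rejectionSample(dt, 0.75)$index, c(4, 2, 1))
  expect_error(rejectionSample(d, 0), "tolerance")
  expect_error(rejectionSample(d, 1.5), "tolerance")
})

test_that("model posteriors are symmetric, separable and sum to one", {
  set.seed(89)
  p <- drawParameters(getModel("A"), n = 2000)
  ## identical generating processes: probabilities near 1/2
  statsA <- matrix(rnorm(2000 * 4), ncol = 4)
  statsB <- matrix(rnorm(2000 * 4), ncol = 4)
  tabs <- list(A = toyTable(p, statsA), B = toyTable(p, statsB))
  post <- modelPosterior(rep(0, 4), tabs, tolerance = 0.2)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_lt(abs(post[["A"]] - 0.5), 0.15)

  ## perfectly separated statistics identify the generating model
  statsB2 <- statsB + 50
  tabs2 <- list(A = toyTable(p, statsA), B = toyTable(p, statsB2))
  post2 <- suppressWarnings(modelPosterior(rep(0, 4), tabs2, tolerance = 0.2))
  expect_gt(post2[["A"]], 0.99)
  post3 <- suppressWarnings(
    modelPosterior(rep(50, 4), tabs2, tolerance = 0.2))
  expect_gt(post3[["B"]], 0.99)
})

test_that("Bayes factors are posterior ratios and compose consistently", {
  bf <- bayesFactors(c(A = 0.5, B = 0.5))
  expect_equal(bf["A", "B"], 1)
  bf2 <- bayesFactors(c(A = 0.8, B = 0.2))
  expect_equal(bf2["A", "B"], 4)
  p <- c(A = 0.6, B = 0.3, C = 0.1)
  bf3 <- bayesFactors(p)
  expect_equal(bf3["A", "B"] * bf3["B", "C"], bf3["A", "C"])
  expect_true(is.infinite(bayesFactors(c(A = 1, B = 0))["A", "B"]))
})

test_that("cross-validation separates distinct models and not identical ones", {
  set.seed(97)
  p <- drawParameters(getModel("A"), n = 1500)
  near <- matrix(rnorm(1500 * 3), ncol = 3)
  far <- matrix(rnorm(1500 * 3, mean = 30), ncol = 3)
  tabs <- list(A = toyTable(p, near), B = toyTable(p, far))
  cv <- crossValidateModelChoice(tabs, tolerance = 0.2, nPseudo = 20)
  expect_equal(unname(rowSums(cv$confusion)), c(20, 20))
  expect_gte(cv$accuracy, 0.95)
  expect_gt(cv$soft["A", "A"], 0.9)

  tabsSame <- list(A = toyTable(p, near),
                   B = toyTable(p, matrix(rnorm(1500 * 3), ncol = 3)))
  cvs <- crossValidateModelChoice(tabsSame, tolerance = 0.2, nPseudo = 20)
  expect_lt(abs(cvs$soft["A", "A"] - 0.5), 0.2)
  expect_lt(abs(cvs$soft["B", "B"] - 0.5), 0.2)
})

test_that("goodness of fit flags outliers and stays in [0, 1]", {
  set.seed(101)
  p <- drawParameters(getModel("A"), n = 2000)
  stats <- matrix(rnorm(2000 * 3), ncol = 3)
  tab <- toyTable(p, stats)
  g1 <- goodnessOfFit(rep(0, 3), tab, tolerance = 0.1, nNull = 200)
  expect_gte(g1$p.value, 0)
  expect_lte(g1$p.value, 1)
  expect_gt(g1$p.value, 0.01)   # a central observation is not rejected
  ## an observation displaced 10 pooled SDs is rejected
  g2 <- goodnessOfFit(rep(10, 3), tab, tolerance = 0.1, nNull = 200)
  expect_lt(g2$p.value, 0.01)
})

test_that("goodness-of-fit p-values are roughly uniform under the model", {
  set.seed(103)
  p <- drawParameters(getModel("A"), n = 500)
  stats <- matrix(rnorm(500 * 3), ncol = 3)
  tab <- toyTable(p, stats)
  pv <- replicate(150, {
    obs <- rnorm(3)
    goodnessOfFit(obs, tab, tolerance = 0.2, nNull = 60)$p.value
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("rejection at tolerance 1 reproduces the prior marginals", {
  set.seed(107)
  mod <- getModel("G")
  p <- drawParameters(mod, n = 4000)
  stats <- matrix(rnorm(4000 * 5), ncol = 5)  # carry no information
  tab <- toyTable(p, stats, model = mod)
  post <- estimateParameters(rnorm(5), tab, tolerance = 1,
                             method = "rejection")
  expect_equal(nrow(post@retained), 4000)
  b <- priorBounds(defaultPriors("nuclear"))
  ## unconstrained marginals are uniform over their prior bounds
  for (par in c("N_C", "N_P", "N_A")) {
    ks <- ks.test(post@retained[, par], "punif", b[[par]][1], b[[par]][2])
    expect_gt(ks$p.value, 0.01)
  }
  s <- posteriorSummary(post)
  expect_lt(abs(s["Weighted Median", "N_C"] - 50005), 3000)
  ## summary rows are ordered and inside the prior support
  expect_true(all(s["Weighted 2.5%", ] <= s["Weighted Median", ]))
  expect_true(all(s["Weighted Median", ] <= s["Weighted 97.5%", ]))
  expect_true(all(s["Minimum", ] >= vapply(
    b[colnames(s)], `[`, 0, 1)))
})

test_that("local-linear adjustment recovers a linear toy parameter", {
  set.seed(109)
  n <- 5000
  theta <- runif(n, 10, 1e5)        # matches the N_C prior support
  stats <- cbind(theta / 1e4 + rnorm(n, sd = 0.05),
                 rnorm(n))          # one informative, one noise statistic
  mod <- getModel("A")
  p <- drawParameters(mod, n = n)
  p[, "N_C"] <- theta
  tab <- toyTable(p, stats, model = mod)
  trueTheta <- 42000
  obs <- c(trueTheta / 1e4, 0)
  post <- estimateParameters(obs, tab, tolerance = 0.1, method = "loclinear")
  med <- posteriorSummary(post)["Weighted Median", "N_C"]
  expect_lt(abs(med - trueTheta) / trueTheta, 0.05)
  ## adjusted draws respect the prior bounds after back-transformation
  expect_true(all(post@adjusted[, "N_C"] >= 10 &
                  post@adjusted[, "N_C"] <= 1e5))
  ## rejection is less sharp than the adjusted fit on the same retained set
  postR <- estimateParameters(obs, tab, tolerance = 0.1, method = "rejection")
  iqr <- function(x) diff(unname(
    posteriorSummary(x)[c("Weighted 2.5%", "Weighted 97.5%"), "N_C"]))
  expect_lt(iqr(post), iqr(postR))
})

test_that("neural-net adjustment is seeded, bounded and sane", {
  set.seed(113)
  n <- 2000
  theta <- runif(n, 10, 1e5)
  stats <- cbind(theta / 1e4 + rnorm(n, sd = 0.1), rnorm(n))
  mod <- getModel("A")
  p <- drawParameters(mod, n = n)
  p[, "N_C"] <- theta
  tab <- toyTable(p, stats, model = mod)
  obs <- c(3, 0)
  set.seed(7)
  a <- estimateParameters(obs, tab, tolerance = 0.2, method = "neuralnet",
                          restarts = 3)
  set.seed(7)
  b <- estimateParameters(obs, tab, tolerance = 0.2, method = "neuralnet",
                          restarts = 3)
  expect_identical(posteriorSummary(a), posteriorSummary(b))
  expect_true(all(a@adjusted >= rep(a@bounds[1, ], each = nrow(a@adjusted)) &
                  a@adjusted <= rep(a@bounds[2, ], each = nrow(a@adjusted))))
  med <- posteriorSummary(a)["Weighted Median", "N_C"]
  expect_lt(abs(med - 30000) / 30000, 0.25)
})

test_that("degenerate regressions fall back to rejection with a warning", {
  set.seed(127)
  mod <- getModel("A")
  p <- drawParameters(mod, n = 500)
  s1 <- rnorm(500)
  stats <- cbind(s1, s1)           # perfectly collinear statistics
  tab <- toyTable(p, stats, model = mod)
  expect_warning(post <- estimateParameters(c(0, 0), tab, tolerance = 0.5,
                                            method = "loclinear"),
                 "falling back to rejection")
  expect_equal(post@method, "rejection")
  expect_equal(post@adjusted, post@retained)
})

test_that("posterior predictive checks bracket reproducible statistics", {
  set.seed(131)
  req <- easyNuclearRequest()
  mod <- getModel("A")
  truth <- c(N_C = 5e4, N_P = 5e4, N_A = 5e4, T_CP = 1e6, T_A = 4e6)
  obs <- simulateStatVector(mod, truth, req)
  tab <- buildReferenceTable(mod, req, 2000)
  post <- estimateParameters(obs, tab, tolerance = 0.1, method = "rejection")
  pp <- posteriorPredictiveCheck(post, mod, req, obs, nRep = 100)
  expect_length(pp, 13)
  expect_true(all(pp >= 0 & pp <= 1))
  ## most tail probabilities are interior for data the model generated
  expect_gte(sum(pp > 0.01 & pp < 0.99), 10)
  ## a statistic forced beyond the simulated range is extreme
  obs2 <- obs; obs2["S_total"] <- 1e6
  pp2 <- posteriorPredictiveCheck(post, mod, req, obs2, nRep = 50)
  expect_equal(unname(pp2["S_total"]), 0)
})
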