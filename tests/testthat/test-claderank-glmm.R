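test_that("phyloCorrelation implements shared-path / max-depth scaling", {
  id <- phyloCorrelation(parseNewick("(A:1,B:1);"), lengths = "given")
  expect_equal(unname(id), diag(2))

  C <- phyloCorrelation(parseNewick("((A:1,B:1):1,C:2);"),
                        lengths = "given")
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), c(1, 1, 1))

  # grafen lengths turn a cladogram into a PSD correlation
  set.seed(31)
  tr <- randomBinaryTree(12, "t")
  G <- phyloCorrelation(tr, lengths = "grafen")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(unname(diag(G)), rep(1, 12))

  expect_error(phyloCorrelation(parseNewick("((A,B),C);"),
                                lengths = "given"), "branch lengths")
})

test_that("gelmanRubin follows the within/between variance formula", {
  set.seed(32)
  x <- rnorm(1000)
  expect_equal(unname(gelmanRubin(list(x, x))), 1, tolerance = 1e-3)
  far <- gelmanRubin(list(rnorm(1000, 0, 1), rnorm(1000, 5, 1)))
  expect_gt(unname(far), 1.1)
  expect_error(gelmanRubin(list(x)), "two chains")
  expect_error(gelmanRubin(list(x, rnorm(500))), "equal length")
})

test_that("a prior-only run reproduces the prior mean of the variances", {
  fx <- enchenopaFixture()
  C <- phyloCorrelation(fx$host, lengths = "grafen")
  # nu = 6, V = 2: scaled inv-chi-squared mean = nu*V/(nu-2) = 3
  fit <- fitPoissonPGLMM(NULL, C, priorSpec(V = 2, nu = 6),
                         nChains = 2L, nIter = 2e4L, burnin = 2e3L,
                         thin = 5L, seed = 12)
  s <- fit@summary
  for (p in c("vPhylo", "vGenus", "vResid")) {
    m <- s$mean[s$parameter == p]
    expect_lt(abs(m - 3), 0.25)  # Monte-Carlo error at ~7200 draws
  }
})

test_that("the sampler recovers a known slope and diagnoses convergence", {
  host <- simulateHostTree(20, seed = 7)
  C <- phyloCorrelation(host, lengths = "grafen")
  tab <- simulateCladeRankTable(host, beta0 = 1, beta1 = 0.5,
                                vPhylo = 0.3, vGenus = 0.1, vResid = 0.1,
                                nPerHost = 5, seed = 201)
  fit <- fitPoissonPGLMM(tab, C, priorSpec(), nChains = 3L,
                         nIter = 1e5L, burnin = 2e4L, thin = 50L,
                         seed = 301)
  s <- fit@summary
  b1 <- s[s$parameter == "beta1", ]
  expect_lt(abs(b1$mean - 0.5), 0.25)
  expect_true(b1$lower95 <= 0.5 && 0.5 <= b1$upper95)
  expect_true(all(fit@psrf < 1.1))
  # CI bounds ordered for every parameter
  expect_true(all(s$lower95 <= s$upper95))
  # every H2 sample strictly inside (0, 1)
  h2 <- phylogeneticHeritability(fit)
  expect_true(all(h2$samples > 0 & h2$samples < 1))
  # chain-merge consistency: merged mean between per-chain means
  perChain <- vapply(fit@samples, function(m) mean(m[, "beta1"]),
                     numeric(1))
  expect_gte(b1$mean, min(perChain) - 1e-12)
  expect_lte(b1$mean, max(perChain) + 1e-12)
})

test_that("H2 tracks the simulated phylogenetic variance share", {
  host <- simulateHostTree(20, seed = 7)
  C <- phyloCorrelation(host, lengths = "grafen")
  strong <- simulateCladeRankTable(host, beta0 = 1, beta1 = 0.2,
                                   vPhylo = 1, vGenus = 0, vResid = 0.1,
                                   nPerHost = 5, seed = 8)
  fitS <- fitPoissonPGLMM(strong, C, priorSpec(), nIter = 5e4L,
                          burnin = 1e4L, thin = 25L, seed = 9)
  expect_gt(phylogeneticHeritability(fitS)$mean, 0.5)

  none <- simulateCladeRankTable(host, beta0 = 1, beta1 = 0.2,
                                 vPhylo = 0, vGenus = 0, vResid = 0.1,
                                 nPerHost = 5, seed = 10)
  fitN <- fitPoissonPGLMM(none, C, priorSpec(), nIter = 5e4L,
                          burnin = 1e4L, thin = 25L, seed = 11)
  expect_lt(phylogeneticHeritability(fitN)$mean, 0.25)
  # the no-genus denominator variant is always >= the full one
  expect_gte(phylogeneticHeritability(fitS, "noGenus")$mean,
             phylogeneticHeritability(fitS)$mean)
})

test_that("configuration errors are caught before sampling", {
  host <- simulateHostTree(6, seed = 1)
  C <- phyloCorrelation(host, lengths = "grafen")
  tab <- simulateCladeRankTable(host, nPerHost = 2, seed = 2)
  expect_error(fitPoissonPGLMM(tab, C, nIter = 100L, burnin = 100L),
               "burnin")
  tab$host[1] <- "missing_taxon"
  expect_error(fitPoissonPGLMM(tab, C, nIter = 1000L, burnin = 100L),
               "index error")
})
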