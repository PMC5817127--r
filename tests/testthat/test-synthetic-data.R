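test_that("simulated host trees are ultrametric Yule trees", {
  tr <- simulateHostTree(8, seed = 1)
  expect_identical(ape::Ntip(tr), 8L)
  expect_identical(tr$Nnode, 7L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  # bit-identical reproduction under the same seed
  expect_identical(writeNewick(simulateHostTree(8, seed = 3),
                               canonical = TRUE),
                   writeNewick(simulateHostTree(8, seed = 3),
                               canonical = TRUE))
  expect_error(simulateHostTree(1), ">= 2")
})

test_that("mean Yule height matches the closed-form expectation", {
  hts <- vapply(seq_len(400), function(i)
    max(ape::node.depth.edgelength(simulateHostTree(10, seed = i))),
    numeric(1))
  expected <- sum(1 / (2:10))
  se <- stats::sd(hts) / sqrt(length(hts))
  expect_lt(abs(mean(hts) - expected), 3 * se)
})

test_that("pure codivergence yields a congruent symbiont tree", {
  for (n in c(5L, 20L, 50L)) {
    h <- simulateHostTree(n, seed = n)
    sim <- simulateCophylogeny(h, pCospeciation = 1, switchRate = 0,
                               duplicationRate = 0, pFtdCherry = 0,
                               seed = n + 1L)
    cv <- countsVector(getEventCounts(sim))
    expect_identical(cv, c(cospeciations = n - 1L, duplications = 0L,
                           switches = 0L, losses = 0L, ftd = 0L))
    r <- reconcile(sim@tanglegram)
    expect_equal(totalCost(r), 0)
    expect_identical(countsVector(getEventCounts(r))[["cospeciations"]],
                     n - 1L)
  }
})

test_that("the true event ledger satisfies the speciation identity", {
  set.seed(51)
  for (rep in seq_len(100)) {
    h <- simulateHostTree(sample(4:12, 1L), seed = 6000 + rep)
    sim <- simulateCophylogeny(
      h, pCospeciation = stats::runif(1),
      switchRate = stats::runif(1, 0, 1.5),
      duplicationRate = stats::runif(1, 0, 0.5),
      pFtdCherry = stats::runif(1, 0, 0.5), seed = 7000 + rep)
    cv <- countsVector(getEventCounts(sim))
    st <- symbiontTree(sim)
    nInternal <- if (ape::Ntip(st) == 1L) 0L else st$Nnode
    expect_identical(cv[["cospeciations"]] + cv[["duplications"]] +
                       cv[["switches"]], nInternal)
    expect_identical(nrow(sim@ledger), sum(cv))
    # associations reference real host tips and cover every symbiont tip
    expect_setequal(names(associations(sim@tanglegram)), st$tip.label)
    expect_true(all(unlist(associations(sim@tanglegram)) %in%
                      h$tip.label))
    validObject(sim@tanglegram)
  }
})

test_that("cophylogeny simulation is reproducible under a seed", {
  h <- simulateHostTree(10, seed = 42)
  a <- simulateCophylogeny(h, seed = 43)
  b <- simulateCophylogeny(h, seed = 43)
  expect_identical(writeNewick(symbiontTree(a), canonical = TRUE),
                   writeNewick(symbiontTree(b), canonical = TRUE))
  expect_identical(associations(a@tanglegram), associations(b@tanglegram))
  expect_identical(a@ledger, b@ledger)
})

test_that("clade-rank tables follow the stated generative model", {
  host <- simulateHostTree(20, seed = 61)
  # beta1 = 0, all variances 0: iid Poisson(exp(beta0))
  tab <- simulateCladeRankTable(host, beta0 = 1, beta1 = 0, vPhylo = 0,
                                vGenus = 0, vResid = 0, nPerHost = 50,
                                seed = 62)
  expect_identical(nrow(tab), 1000L)
  mu <- exp(1)
  se <- sqrt(mu / nrow(tab))
  expect_lt(abs(mean(tab$symbiont_rank) - mu), 3 * se)
  # responses are non-negative integers; hosts index the tree
  expect_true(all(tab$symbiont_rank >= 0 &
                    tab$symbiont_rank == round(tab$symbiont_rank)))
  expect_true(all(tab$host %in% host$tip.label))
  expect_identical(tab$host_rank,
                   cladeRank(host, tab$host))
  # determinism
  expect_identical(tab, simulateCladeRankTable(host, beta0 = 1,
                                               beta1 = 0, vPhylo = 0,
                                               vGenus = 0, vResid = 0,
                                               nPerHost = 50, seed = 62))
  # genus blocks group tips and are non-empty
  expect_true(all(nchar(tab$genus) > 0))
})

test_that("the packaged host tree matches the published structure", {
  fx <- enchenopaFixture()
  host <- fx$host
  expect_identical(ape::Ntip(host), 15L)
  expect_true(isBinary <- host$Nnode == 14L)
  sisters <- function(a, b) {
    m <- ape::getMRCA(host, c(a, b))
    desc <- ape::extract.clade(host, m)$tip.label
    setequal(desc, c(a, b))
  }
  expect_true(sisters("Viburnum prunifolium", "Viburnum rufidulum"))
  expect_true(sisters("Juglans nigra", "Juglans cinerea"))
  expect_true(sisters("Sideroxylon lycioides", "Sideroxylon lanuginosum"))
  # Carya joins the Juglans pair within Fagales
  fagales <- ape::extract.clade(
    host, ape::getMRCA(host, c("Carya", "Juglans nigra")))
  expect_setequal(fagales$tip.label,
                  c("Carya", "Juglans nigra", "Juglans cinerea"))
  # Viburnum ladder: lentago joins the closest pair before cassinoides
  vib <- ape::extract.clade(
    host, ape::getMRCA(host, c("Viburnum lentago",
                               "Viburnum prunifolium")))
  expect_setequal(vib$tip.label, c("Viburnum lentago",
                                   "Viburnum prunifolium",
                                   "Viburnum rufidulum"))
  # every complex host in the table is a tip of the tree
  complex <- fx$associations[fx$associations$species == "E. binotata", ]
  expect_true(all(unlist(complex$hosts) %in% host$tip.label))
})

test_that("the fixture assembles into the study tanglegram", {
  fx <- enchenopaFixture()
  set.seed(71)
  symbiont <- randomBinaryTree(61, "EN")
  symbiont$tip.label <- fx$associations$symbiont_tip  # synthetic topology
  expect_message(
    tg <- buildTanglegram(fx$host, symbiont, fx$associations,
                          dropUnmapped = TRUE),
    "dropped 17")
  expect_identical(ape::Ntip(symbiontTree(tg)), 44L)
  expect_true(all(lengths(associations(tg)) > 0L))
})
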