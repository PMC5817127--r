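cong3tg <- function() {
  buildTanglegram(parseNewick("((h1,h2),h3);"),
                  parseNewick("((p1,p2),p3);"),
                  list(p1 = "h1", p2 = "h2", p3 = "h3"))
}

test_that("random tip mapping is seeded, valid and uniform", {
  tg <- cong3tg()
  a <- randomTipMapping(tg, seed = 5)
  b <- randomTipMapping(tg, seed = 5)
  expect_identical(associations(a), associations(b))

  hosts <- hostTree(tg)$tip.label
  draws <- matrix("", nrow = 3000L, ncol = 3L)
  set.seed(99)
  for (i in seq_len(nrow(draws))) {
    m <- associations(randomTipMapping(tg))
    expect_true(all(lengths(m) == 1L))
    expect_true(all(unlist(m) %in% hosts))
    draws[i, ] <- unlist(m)
  }
  # per-tip selection frequency of each host within 3 binomial SE of 1/3
  se <- sqrt((1 / 3) * (2 / 3) / nrow(draws))
  for (col in 1:3)
    for (h in hosts)
      expect_lt(abs(mean(draws[, col] == h) - 1 / 3), 3 * se + 1e-12)
})

test_that("permute-observed variant preserves the host multiset", {
  tg <- cong3tg()
  p <- randomTipMapping(tg, seed = 3, model = "permute_observed")
  expect_identical(sort(unname(unlist(associations(p)))),
                   sort(unname(unlist(associations(tg)))))
})

test_that("exhaustive permutation test is exact on the congruent case", {
  tg <- cong3tg()
  res <- permutationTest(tg, eventCosts(), mode = "exhaustive")
  expect_equal(pValue(res), 2 / 27)
  expect_identical(res@nPermutations, 27L)
  expect_equal(res@observedCost, 0)
  # two mappings attain cost 0: the two orientations of the cherry
  expect_identical(sum(res@nullCosts <= 1e-9), 2L)
})

test_that("monte-carlo p agrees with the exhaustive value", {
  tg <- cong3tg()
  exact <- 2 / 27
  res <- permutationTest(tg, eventCosts(), nPermutations = 999L,
                         seed = 11, mode = "monte_carlo")
  # 99% binomial interval around the exhaustive p (+1 smoothing margin)
  half <- stats::qnorm(0.995) * sqrt(exact * (1 - exact) / 999) + 1 / 1000
  expect_lt(abs(pValue(res) - exact), half)
  expect_gt(pValue(res), 0)
  expect_lte(pValue(res), 1)
})

test_that("an observed mapping that is worst possible gives p = 1", {
  tg <- cong3tg()
  ex <- permutationTest(tg, eventCosts(), mode = "exhaustive")
  worst <- which.max(ex@nullCosts)
  grid <- as.matrix(expand.grid(rep(list(1:3), 3)))
  hosts <- hostTree(tg)$tip.label
  assoc <- as.list(hosts[grid[worst, ]])
  names(assoc) <- symbiontTree(tg)$tip.label
  tgWorst <- tanglegram(hostTree(tg), symbiontTree(tg), assoc)
  res <- permutationTest(tgWorst, eventCosts(), mode = "exhaustive")
  expect_equal(pValue(res), 1)
})

test_that("null costs are invariant to association row order", {
  h <- parseNewick("((h1,h2),(h3,h4));")
  s <- parseNewick("((p1,p2),(p3,p4));")
  tab <- data.frame(symbiont_tip = c("p1", "p2", "p3", "p4"),
                    host = c("h1", "h2", "h3", "h4"))
  tg1 <- buildTanglegram(h, s, asAssociationTable(tab))
  tg2 <- buildTanglegram(h, s, asAssociationTable(tab[c(3, 1, 4, 2), ]))
  r1 <- permutationTest(tg1, eventCosts(), nPermutations = 99L, seed = 4)
  r2 <- permutationTest(tg2, eventCosts(), nPermutations = 99L, seed = 4)
  expect_identical(r1@nullCosts, r2@nullCosts)
  expect_identical(pValue(r1), pValue(r2))
})

test_that("exhaustive mode enforces its size guard", {
  set.seed(21)
  h <- randomBinaryTree(10, "h")
  s <- randomBinaryTree(7, "p")
  assoc <- as.list(sample(h$tip.label, 7, replace = TRUE))
  names(assoc) <- s$tip.label
  tg <- tanglegram(h, s, assoc)
  expect_error(permutationTest(tg, mode = "exhaustive"), "size error")
})
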