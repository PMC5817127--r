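cong3 <- function() {
  buildTanglegram(parseNewick("((h1,h2),h3);"),
                  parseNewick("((p1,p2),p3);"),
                  list(p1 = "h1", p2 = "h2", p3 = "h3"))
}

test_that("reconcile handles the canonical small cases", {
  # fully congruent: two free cospeciations
  r <- reconcile(cong3())
  expect_equal(totalCost(r), 0)
  expect_identical(countsVector(getEventCounts(r)),
                   c(cospeciations = 2L, duplications = 0L, switches = 0L,
                     losses = 0L, ftd = 0L))

  # one tip swapped: one cospeciation plus one switch
  tg <- buildTanglegram(parseNewick("((h1,h2),h3);"),
                        parseNewick("((p1,p3),p2);"),
                        list(p1 = "h1", p2 = "h2", p3 = "h3"))
  r2 <- reconcile(tg)
  expect_equal(totalCost(r2), 1)
  cv <- countsVector(getEventCounts(r2))
  expect_identical(cv[["cospeciations"]], 1L)
  expect_identical(cv[["switches"]], 1L)

  # both symbionts on one host: a duplication
  tgd <- tanglegram(parseNewick("(h1,h2);"), parseNewick("(a,b);"),
                    list(a = "h1", b = "h1"))
  r3 <- reconcile(tgd)
  expect_equal(totalCost(r3), 1)
  expect_identical(countsVector(getEventCounts(r3))[["duplications"]], 1L)

  # single widespread tip spanning a host cherry: one failure to diverge
  tgw <- tanglegram(parseNewick("(h1,h2);"), parseNewick("(w);"),
                    list(w = c("h1", "h2")))
  r4 <- reconcile(tgw)
  expect_equal(totalCost(r4), 1)
  expect_identical(countsVector(getEventCounts(r4))[["ftd"]], 1L)
})

test_that("widespread tips are charged by the spanning-subtree rule", {
  # hosts {h1, h3} span the whole 3-tip tree: 2 ftd + 1 loss toward h2
  h <- parseNewick("((h1,h2),h3);")
  tg <- tanglegram(h, parseNewick("(w);"), list(w = c("h1", "h3")))
  r <- reconcile(tg)
  cv <- countsVector(getEventCounts(r))
  expect_identical(cv[["ftd"]], 2L)
  expect_identical(cv[["losses"]], 1L)
  expect_equal(totalCost(r), 3)
})

test_that("the DP solver matches the brute-force oracle exactly", {
  set.seed(11)
  for (rep in seq_len(60)) {
    tg <- randomTanglegram(sample(3:6, 1L), sample(3:6, 1L))
    cs <- randomCosts()
    expect_equal(totalCost(reconcile(tg, cs)),
                 bruteForceReconcile(tg, cs)$totalCost,
                 info = paste("replicate", rep))
  }
  # and with widespread tips under default costs
  for (rep in seq_len(40)) {
    tg <- randomTanglegram(sample(3:6, 1L), sample(2:5, 1L),
                           widespread = TRUE)
    expect_equal(totalCost(reconcile(tg)),
                 bruteForceReconcile(tg)$totalCost)
  }
})

test_that("the oracle refuses instances beyond its guard rail", {
  set.seed(12)
  tg <- randomTanglegram(8, 4)
  expect_error(bruteForceReconcile(tg), "size error")
})

test_that("event counts always satisfy the speciation identity", {
  set.seed(13)
  for (rep in seq_len(30)) {
    tg <- randomTanglegram(sample(3:7, 1L), sample(2:7, 1L),
                           widespread = rep %% 3L == 0L)
    r <- reconcile(tg, randomCosts())
    cv <- countsVector(getEventCounts(r))
    expect_identical(cv[["cospeciations"]] + cv[["duplications"]] +
                       cv[["switches"]],
                     symbiontTree(tg)$Nnode)
    # self-consistency: total equals counts . costs (validity invariant)
    expect_equal(totalCost(r), sum(cv * costsVector(r@costs)))
  }
})

test_that("congruent tanglegrams cost (n-1) * tracking with no shifts", {
  set.seed(14)
  n <- 20L
  tr <- randomBinaryTree(n, "h")
  s <- tr
  s$tip.label <- sub("^h", "p", s$tip.label)
  assoc <- as.list(tr$tip.label)
  names(assoc) <- s$tip.label
  tg <- tanglegram(tr, s, assoc)
  for (cs in costSchemes()) {
    r <- reconcile(tg, cs)
    cv <- countsVector(getEventCounts(r))
    expect_identical(cv[["cospeciations"]], n - 1L)
    expect_identical(cv[["switches"]], 0L)
    expect_identical(cv[["losses"]], 0L)
    expect_identical(cv[["duplications"]], 0L)
    expect_equal(totalCost(r), (n - 1) * costsVector(cs)[["tracking"]])
  }
})

test_that("optimal cost is monotone in each cost component", {
  set.seed(15)
  for (rep in seq_len(8)) {
    tg <- randomTanglegram(sample(4:6, 1L), sample(4:6, 1L))
    base <- c(tracking = 0, duplication = 1, switch = 1, loss = 1, ftd = 1)
    for (comp in names(base)) {
      prev <- -Inf
      for (v in c(0, 1, 2)) {
        cs <- base; cs[comp] <- v
        tc <- totalCost(reconcile(tg, do.call(eventCosts, as.list(cs))))
        expect_gte(tc, prev - 1e-9)
        prev <- tc
      }
    }
  }
})

test_that("enumerateOptima is deterministic, complete and capped", {
  # congruent tanglegram has a unique optimum
  expect_length(enumerateOptima(cong3()), 1L)

  # two-tip symbiont on a 3-tip host: the cospeciation-with-loss optimum
  # plus the two switch orientations
  tg <- tanglegram(parseNewick("((h1,h2),h3);"), parseNewick("(p1,p2);"),
                   list(p1 = "h1", p2 = "h3"))
  opt <- enumerateOptima(tg)
  expect_length(opt, 3L)
  expect_true(all(vapply(opt, totalCost, numeric(1)) == 1))
  events <- vapply(opt, function(o)
    o@placements$event[o@placements$event != "tip"][1], character(1))
  expect_setequal(unique(events), c("cospeciation", "switch"))
  expect_identical(bruteForceReconcile(tg)$nOptima, 3L)

  # truncation
  expect_length(enumerateOptima(tg, limit = 1L), 1L)

  # enumeration counts agree with the oracle on random instances
  set.seed(16)
  for (rep in seq_len(25)) {
    tgr <- randomTanglegram(sample(3:5, 1L), sample(2:4, 1L))
    expect_identical(length(enumerateOptima(tgr, limit = 100000L)),
                     bruteForceReconcile(tgr)$nOptima)
  }
})

test_that("costSweep tabulates schemes with non-decreasing optima", {
  set.seed(17)
  tg <- randomTanglegram(5, 5)
  sw <- costSweep(tg)
  expect_identical(nrow(sw), 3L)
  expect_true(all(diff(sw$totalCost) >= -1e-9))
  expect_true(all(sw$nOptima >= 1L))
  # congruent input: every scheme reports pure tracking
  tgc <- cong3()
  swc <- costSweep(tgc)
  expect_true(all(swc$cospeciations == 2L))
  expect_true(all(swc$switches == 0L))
})

test_that("degenerate and invalid inputs are rejected or closed-form", {
  h <- parseNewick("((h1,h2),h3);")
  # single-tip symbiont with a single host: trivial zero-cost embedding
  tg1 <- tanglegram(h, parseNewick("(only);"), list(only = "h2"))
  expect_equal(totalCost(reconcile(tg1)), 0)
  # association to a non-tip label is caught at construction
  expect_error(tanglegram(h, parseNewick("(p1,p2);"),
                          list(p1 = "h1", p2 = "zzz")) |> validObject(),
               "not in host tree")
})
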