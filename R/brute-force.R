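## Verification oracle: exhaustive enumeration over complete placement
## vectors. Independent of the dynamic program in reconcile.R: for every
## assignment of each internal symbiont node to a host position, the local
## event cost at a node is read off a precomputed (parent, child1, child2)
## table and summed; the minimum over all assignments is the optimum by
## definition. Guard-railed to small instances.

#' Brute-force reconciliation oracle
#'
#' Exhaustively enumerates all event-consistent embeddings of the symbiont
#' tree into the host tree (every assignment of internal symbiont nodes to
#' host positions, tips fixed by their associations) and returns the
#' minimum total cost, the number of cost-optimal embeddings (placements
#' combined with event-label choices), and one optimal placement. Intended
#' as an independent check of [reconcile()]; refuses instances with more
#' than 7 tips in either tree.
#'
#' @inheritParams reconcile
#' @return a list with elements `totalCost`, `nOptima`, and `placements`
#'   (data.frame of one optimal assignment: symbiont node, host position)
#' @export
bruteForceReconcile <- function(tg, costs = eventCosts(),
                                switchConstraint = c("incomparable",
                                                     "unconstrained")) {
  switchConstraint <- match.arg(switchConstraint)
  stopifnot(is(tg, "Tanglegram"), is(costs, "EventCosts"))
  host <- tg@host; sym <- tg@symbiont
  if (length(host$tip.label) > 7L || length(sym$tip.label) > 7L)
    stop("size error: brute-force oracle is limited to 7 tips per tree")
  if (length(sym$tip.label) == 1L) {
    r <- singleTipReconciliation(tg, costs)
    return(list(totalCost = r@totalCost, nOptima = 1L,
                placements = r@placements[c("symbiont", "hostPosition")]))
  }
  hidx <- treeIndex(host); sidx <- treeIndex(sym)
  nh <- hidx$n
  D <- subtreeMatrix(hidx)
  allowed <- if (switchConstraint == "incomparable") !(D | t(D)) else
    !(diag(nh) > 0)
  dist <- matrix(Inf, nh, nh)
  for (x in seq_len(nh))
    dist[x, D[x, ]] <- hidx$depth[D[x, ]] - hidx$depth[x]

  cT <- costs@tracking; cD <- costs@duplication; cS <- costs@switch
  cL <- costs@loss; cF <- costs@ftd

  # local event-cost and event-multiplicity tables F[h, a, b], M[h, a, b]
  F <- array(Inf, dim = c(nh, nh, nh))
  M <- array(0L, dim = c(nh, nh, nh))
  for (h in seq_len(nh)) {
    hk <- hidx$children[[h]]
    for (a in seq_len(nh)) {
      for (b in seq_len(nh)) {
        vals <- numeric(0)
        if (length(hk) == 2L) {
          l <- hk[1]; r <- hk[2]
          if (D[l, a] && D[r, b])
            vals <- c(vals, cT + cL * (dist[l, a] + dist[r, b]))
          if (D[r, a] && D[l, b])
            vals <- c(vals, cT + cL * (dist[r, a] + dist[l, b]))
        }
        if (D[h, a] && D[h, b])
          vals <- c(vals, cD + cL * (dist[h, a] + dist[h, b]))
        if (D[h, a] && allowed[h, b])
          vals <- c(vals, cS + cL * dist[h, a])
        if (D[h, b] && allowed[h, a])
          vals <- c(vals, cS + cL * dist[h, b])
        if (length(vals)) {
          F[h, a, b] <- min(vals)
          M[h, a, b] <- sum(vals <= min(vals) + RECTOL)
        }
      }
    }
  }

  # fixed tip placements and widespread intrinsic charges
  fixedPos <- integer(sidx$n)
  intrinsic <- 0
  for (i in seq_len(sidx$ntip)) {
    hids <- match(tg@assoc[[sym$tip.label[i]]], host$tip.label)
    if (length(hids) == 1L) {
      fixedPos[i] <- hids
    } else {
      sp <- spanningInfo(hidx, D, hids)
      fixedPos[i] <- sp$mrca
      intrinsic <- intrinsic + sp$nftd * cF + sp$nleave * cL
    }
  }

  internals <- setdiff(seq_len(sidx$n), seq_len(sidx$ntip))
  k <- length(internals)
  kidMat <- t(vapply(internals, function(p) sidx$children[[p]],
                     integer(2)))

  best <- Inf; nOpt <- 0; bestCombo <- NULL
  # chunk over the first internal node's position to bound memory
  firstRange <- seq_len(nh)
  restGrid <- if (k > 1L)
    as.matrix(expand.grid(rep(list(seq_len(nh)), k - 1L),
                          KEEP.OUT.ATTRS = FALSE)) else
    matrix(integer(0), nrow = 1L, ncol = 0L)
  for (h1 in firstRange) {
    combos <- cbind(h1, restGrid)
    pos <- matrix(0L, nrow(combos), sidx$n)
    pos[, internals] <- combos
    for (i in seq_len(sidx$ntip)) pos[, i] <- fixedPos[i]
    tot <- rep(intrinsic, nrow(combos))
    mult <- rep(1, nrow(combos))
    for (j in seq_len(k)) {
      hp <- pos[, internals[j]]
      ha <- pos[, kidMat[j, 1]]
      hb <- pos[, kidMat[j, 2]]
      lin <- hp + (ha - 1L) * nh + (hb - 1L) * nh * nh
      tot <- tot + F[lin]
      mult <- mult * M[lin]
    }
    m <- min(tot)
    if (m < best - RECTOL) {
      best <- m; nOpt <- 0; bestCombo <- NULL
    }
    if (m <= best + RECTOL) {
      hit <- which(tot <= best + RECTOL)
      nOpt <- nOpt + sum(mult[hit])
      if (is.null(bestCombo)) bestCombo <- pos[hit[1], ]
    }
  }

  placements <- data.frame(
    symbiont = vapply(seq_len(sidx$n), function(p)
      symbiontNodeLabel(sidx, sym$tip.label, p), character(1)),
    hostPosition = vapply(seq_len(sidx$n), function(p)
      hostPositionLabel(hidx, host$tip.label, bestCombo[p]), character(1)),
    stringsAsFactors = FALSE)
  list(totalCost = best, nOptima = as.integer(nOpt),
       placements = placements)
}
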