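## Exact event-based cophylogenetic reconciliation.
##
## Semantics (untimed host tree): a symbiont node "placed at" host node h
## sits on the host edge directly above h. Events at an internal symbiont
## node with children q1, q2 placed at h:
##   cospeciation  h internal with children l, r; q1 and q2 descend into
##                 the two distinct child subtrees
##   duplication   both children continue on the edge above h and descend
##                 within the subtree of h
##   switch        one child stays and descends within subtree(h); the
##                 other jumps to a host edge that is (default) neither an
##                 ancestor nor a descendant of h
## Every host speciation crossed by a descending lineage without an event
## costs one loss. A widespread tip (two or more associated hosts)
## occupies the minimal host subtree spanning its hosts: one
## failure-to-diverge per internal node of that spanning subtree, one loss
## per edge leaving it. The symbiont root may start on any host position
## with no charges above its starting point.
##
## The solver is an exact dynamic program over symbiont x host positions
## with "enter-subtree" (DOWN) and "jump-out" (OUT) auxiliary tables; at
## these problem sizes exactness is affordable and strictly stronger than
## the genetic-algorithm searches of the classic tools.

RECTOL <- 1e-7

#' Minimum-cost reconciliation of a tanglegram
#'
#' Finds a minimum-total-cost embedding of the symbiont tree into the host
#' tree under the five-event model (cospeciation, duplication, host
#' switch, loss, failure to diverge) and the supplied event costs. The
#' solver is exact and deterministic; ties are broken in a fixed order
#' (cospeciation < duplication < switch, then by canonical host-position
#' label).
#'
#' @param tg a [Tanglegram-class]
#' @param costs an [EventCosts-class] (default [eventCosts()])
#' @param switchConstraint "incomparable" (default; switch targets must be
#'   neither ancestors nor descendants of the source position, the weakest
#'   constraint that bars time travel along a single host lineage) or
#'   "unconstrained". Global time consistency across multiple switches is
#'   not enforced, as in most untimed reconciliation solvers.
#' @return a [Reconciliation-class]
#' @examples
#' tg <- buildTanglegram(parseNewick("((h1,h2),h3);"),
#'                       parseNewick("((p1,p2),p3);"),
#'                       list(p1 = "h1", p2 = "h2", p3 = "h3"))
#' reconcile(tg, eventCosts())
#' @export
reconcile <- function(tg, costs = eventCosts(),
                      switchConstraint = c("incomparable", "unconstrained")) {
  switchConstraint <- match.arg(switchConstraint)
  stopifnot(is(tg, "Tanglegram"), is(costs, "EventCosts"))
  validObject(tg); validObject(costs)
  if (length(tg@symbiont$tip.label) == 1L)
    return(singleTipReconciliation(tg, costs))
  eng <- reconcileEngine(tg, costs, switchConstraint)
  sol <- backtrackOne(eng)
  makeReconciliation(tg, costs, sol, eng)
}

#' Enumerate cost-optimal reconciliations
#'
#' Returns up to `limit` distinct minimum-cost reconciliations, in a
#' deterministic backtracking order: at every decision point events are
#' explored as cospeciation < duplication < switch, host positions in
#' canonical order (smallest descendant tip label, ancestors first), and
#' on descent paths "stop here" before "descend further".
#'
#' @inheritParams reconcile
#' @param limit maximum number of reconciliations to return
#' @return a list of [Reconciliation-class] objects, all sharing the
#'   optimal total cost
#' @export
enumerateOptima <- function(tg, costs = eventCosts(), limit = 1000L,
                            switchConstraint = c("incomparable",
                                                 "unconstrained")) {
  switchConstraint <- match.arg(switchConstraint)
  stopifnot(is(tg, "Tanglegram"), is(costs, "EventCosts"),
            limit >= 1L)
  validObject(tg); validObject(costs)
  if (length(tg@symbiont$tip.label) == 1L)
    return(list(singleTipReconciliation(tg, costs)))
  eng <- reconcileEngine(tg, costs, switchConstraint)
  sols <- enumerateAll(eng, as.integer(limit))
  lapply(sols, function(s) makeReconciliation(tg, costs, s, eng))
}

#' Cost-scheme sweep
#'
#' Runs [reconcile()] under a list of cost schemes and tabulates, per
#' scheme, the event counts of one optimum, the optimal total cost, and
#' the number of distinct optima up to a cap. This mirrors the standard
#' sensitivity analysis in which the host-shift cost is varied while
#' cospeciation stays free.
#'
#' @inheritParams reconcile
#' @param schemes non-empty named list of [EventCosts-class] objects
#'   (default [costSchemes()])
#' @param optimaCap cap for the optimum count column
#' @return a data.frame with one row per scheme: scheme, tracking/
#'   duplication/switch/loss/ftd costs, the five event counts, totalCost,
#'   and nOptima (capped)
#' @export
costSweep <- function(tg, schemes = costSchemes(), optimaCap = 1000L,
                      switchConstraint = c("incomparable",
                                           "unconstrained")) {
  switchConstraint <- match.arg(switchConstraint)
  if (!length(schemes)) stop("schemes must be a non-empty list")
  if (is.null(names(schemes)))
    names(schemes) <- paste0("scheme", seq_along(schemes))
  rows <- lapply(names(schemes), function(nm) {
    cs <- schemes[[nm]]
    opt <- enumerateOptima(tg, cs, limit = optimaCap,
                           switchConstraint = switchConstraint)
    cnt <- countsVector(getEventCounts(opt[[1]]))
    cost <- costsVector(cs)
    names(cost) <- paste0(names(cost), "Cost")
    data.frame(scheme = nm, t(cost), t(cnt),
               totalCost = totalCost(opt[[1]]),
               nOptima = length(opt), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- engine ------------------------------------------------------------

reconcileEngine <- function(tg, costs, switchConstraint) {
  host <- tg@host; sym <- tg@symbiont
  hidx <- treeIndex(host); sidx <- treeIndex(sym)
  nh <- hidx$n; np <- sidx$n
  D <- subtreeMatrix(hidx)
  allowed <- if (switchConstraint == "incomparable") !(D | t(D)) else
    !diag(nh) > 0
  lossC <- costs@loss
  C <- matrix(Inf, np, nh)
  DOWN <- matrix(Inf, np, nh)
  wide <- vector("list", np)
  hostPost <- rev(hidx$preorder)

  downFrom <- function(crow) {
    d <- crow
    for (v in hostPost) {
      kids <- hidx$children[[v]]
      if (length(kids))
        d[v] <- min(d[v], min(d[kids]) + lossC)
    }
    d
  }
  minOr <- function(x) if (length(x)) min(x) else Inf

  for (i in seq_len(sidx$ntip)) {
    hids <- match(tg@assoc[[sym$tip.label[i]]], host$tip.label)
    if (length(hids) == 1L) {
      C[i, hids] <- 0
    } else {
      sp <- spanningInfo(hidx, D, hids)
      wide[[i]] <- sp
      C[i, sp$mrca] <- sp$nftd * costs@ftd + sp$nleave * lossC
    }
  }

  OUT <- vector("list", np)  # filled per node when needed
  outRow <- function(q) {
    vapply(seq_len(nh), function(h) minOr(C[q, allowed[h, ]]), numeric(1))
  }

  for (p in rev(sidx$preorder)) {
    if (p <= sidx$ntip) {
      DOWN[p, ] <- downFrom(C[p, ])
      next
    }
    kids <- sidx$children[[p]]
    q1 <- kids[1]; q2 <- kids[2]
    d1 <- DOWN[q1, ]; d2 <- DOWN[q2, ]
    o1 <- outRow(q1); o2 <- outRow(q2)
    OUT[[q1]] <- o1; OUT[[q2]] <- o2
    cc <- rep(Inf, nh)
    for (h in seq_len(nh)) {
      best <- costs@duplication + d1[h] + d2[h]
      hk <- hidx$children[[h]]
      if (length(hk) == 2L) {
        l <- hk[1]; r <- hk[2]
        best <- min(best, costs@tracking +
                      min(d1[l] + d2[r], d1[r] + d2[l]))
      }
      best <- min(best, costs@switch + min(d1[h] + o2[h], d2[h] + o1[h]))
      cc[h] <- best
    }
    C[p, ] <- cc
    DOWN[p, ] <- downFrom(cc)
  }

  canon <- canonicalNodeOrder(hidx)
  list(tg = tg, costs = costs, hidx = hidx, sidx = sidx, D = D,
       allowed = allowed, C = C, DOWN = DOWN, OUT = OUT, wide = wide,
       canon = canon, optCost = min(C[sidx$root, ]))
}

# spanning subtree of a widespread tip's host set: mrca, failure-to-diverge
# count (internal nodes of the spanning subtree), losses (edges leaving it)
spanningInfo <- function(hidx, D, hids) {
  cand <- which(vapply(seq_len(hidx$n), function(v) all(D[v, hids]),
                       logical(1)))
  mrca <- cand[which.max(hidx$depth[cand])]
  span <- unique(unlist(lapply(hids, function(t) {
    path <- t
    while (t != mrca) { t <- hidx$parent[t]; path <- c(path, t) }
    path
  })))
  inSpan <- logical(hidx$n); inSpan[span] <- TRUE
  nftd <- sum(span %in% setdiff(span, hids))
  nleave <- sum(vapply(span, function(v)
    sum(!inSpan[hidx$children[[v]]]), numeric(1)))
  list(mrca = mrca, span = span, nftd = as.integer(nftd),
       nleave = as.integer(nleave))
}

hostPositionLabel <- function(hidx, tipLabels, h) {
  if (h <= hidx$ntip) tipLabels[h] else
    paste0("mrca:", hidx$minTip[h], "+d", hidx$depth[h])
}

symbiontNodeLabel <- function(sidx, tipLabels, p) {
  if (p <= sidx$ntip) tipLabels[p] else
    paste0("node:", sidx$minTip[p], "+d", sidx$depth[p])
}

## ---- single deterministic backtrack ------------------------------------

backtrackOne <- function(eng) {
  root <- eng$sidx$root
  h0 <- eng$canon[which(eng$C[root, eng$canon] <=
                          eng$optCost + RECTOL)[1]]
  sol <- btNode(eng, root, h0)
  stopifnot(abs(solCost(sol, eng$costs) - eng$optCost) < 1e-6)
  sol
}

emptySol <- function() list(rows = list(),
                            counts = c(cosp = 0L, dup = 0L, sw = 0L,
                                       loss = 0L, ftd = 0L))

addRow <- function(sol, row) { sol$rows[[length(sol$rows) + 1L]] <- row; sol }

bumpCounts <- function(sol, ...) {
  inc <- c(...)
  sol$counts[names(inc)] <- sol$counts[names(inc)] + inc
  sol
}

mergeSol <- function(a, b) {
  a$rows <- c(a$rows, b$rows)
  a$counts <- a$counts + b$counts
  a
}

solCost <- function(sol, costs) {
  sum(sol$counts * c(costs@tracking, costs@duplication, costs@switch,
                     costs@loss, costs@ftd))
}

# reconstruct one optimal solution for symbiont node p placed at host h
btNode <- function(eng, p, h) {
  sidx <- eng$sidx; hidx <- eng$hidx; costs <- eng$costs
  target <- eng$C[p, h]
  if (p <= sidx$ntip) {
    sp <- eng$wide[[p]]
    sol <- emptySol()
    if (is.null(sp)) {
      sol <- addRow(sol, list(sym = p, event = "tip", hostPos = h,
                              target = NA_integer_, losses = 0L))
    } else {
      sol <- addRow(sol, list(sym = p, event = "widespread", hostPos = h,
                              target = NA_integer_, losses = sp$nleave))
      sol <- bumpCounts(sol, ftd = sp$nftd, loss = sp$nleave)
    }
    return(sol)
  }
  kids <- sidx$children[[p]]
  q1 <- kids[1]; q2 <- kids[2]
  d1 <- eng$DOWN[q1, ]; d2 <- eng$DOWN[q2, ]
  hk <- hidx$children[[h]]
  # cospeciation first
  if (length(hk) == 2L) {
    l <- hk[1]; r <- hk[2]
    for (orient in list(c(l, r), c(r, l))) {
      val <- costs@tracking + d1[orient[1]] + d2[orient[2]]
      if (val <= target + RECTOL) {
        s1 <- btDown(eng, q1, orient[1])
        s2 <- btDown(eng, q2, orient[2])
        sol <- bumpCounts(mergeSol(mergeSol(emptySol(), s1$sol), s2$sol),
                          cosp = 1L, loss = s1$losses + s2$losses)
        sol <- addRow(sol, list(sym = p, event = "cospeciation",
                                hostPos = h, target = NA_integer_,
                                losses = s1$losses + s2$losses))
        return(sol)
      }
    }
  }
  if (costs@duplication + d1[h] + d2[h] <= target + RECTOL) {
    s1 <- btDown(eng, q1, h); s2 <- btDown(eng, q2, h)
    sol <- bumpCounts(mergeSol(mergeSol(emptySol(), s1$sol), s2$sol),
                      dup = 1L, loss = s1$losses + s2$losses)
    sol <- addRow(sol, list(sym = p, event = "duplication", hostPos = h,
                            target = NA_integer_,
                            losses = s1$losses + s2$losses))
    return(sol)
  }
  o1 <- eng$OUT[[q1]]; o2 <- eng$OUT[[q2]]
  for (jump in 1:2) {
    stay <- if (jump == 1L) q2 else q1
    jq <- if (jump == 1L) q1 else q2
    dstay <- if (jump == 1L) d2[h] else d1[h]
    oj <- if (jump == 1L) o1[h] else o2[h]
    if (costs@switch + dstay + oj <= target + RECTOL) {
      land <- eng$canon[eng$allowed[h, eng$canon] &
                          eng$C[jq, eng$canon] <= oj + RECTOL][1]
      ss <- btDown(eng, stay, h)
      sj <- btNode(eng, jq, land)
      sol <- bumpCounts(mergeSol(mergeSol(emptySol(), ss$sol), sj),
                        sw = 1L, loss = ss$losses)
      sol <- addRow(sol, list(sym = p, event = "switch", hostPos = h,
                              target = land, losses = ss$losses))
      return(sol)
    }
  }
  stop("internal error: backtracking found no event achieving C[p, h]")
}

# follow the DOWN chain of symbiont node p entering the subtree at host v
btDown <- function(eng, p, v) {
  losses <- 0L
  repeat {
    if (eng$C[p, v] <= eng$DOWN[p, v] + RECTOL)
      return(list(sol = btNode(eng, p, v), losses = losses))
    kids <- eng$hidx$children[[v]]
    kids <- kids[order(match(kids, eng$canon))]
    nxt <- kids[eng$DOWN[p, kids] + eng$costs@loss <=
                  eng$DOWN[p, v] + RECTOL][1]
    losses <- losses + 1L
    v <- nxt
  }
}

## ---- full enumeration with cap -----------------------------------------

enumerateAll <- function(eng, limit) {
  root <- eng$sidx$root
  memoN <- new.env(parent = emptyenv())
  memoD <- new.env(parent = emptyenv())
  out <- list()
  for (h in eng$canon) {
    if (eng$C[root, h] > eng$optCost + RECTOL) next
    sols <- enumNode(eng, root, h, limit - length(out), memoN, memoD)
    out <- c(out, sols)
    if (length(out) >= limit) break
  }
  out[seq_len(min(length(out), limit))]
}

crossMerge <- function(listA, listB, cap, post = identity) {
  out <- list()
  for (a in listA) {
    for (b in listB) {
      out[[length(out) + 1L]] <- post(mergeSol(a, b))
      if (length(out) >= cap) return(out)
    }
  }
  out
}

enumNode <- function(eng, p, h, cap, memoN, memoD) {
  if (cap <= 0L) return(list())
  key <- paste0(p, ".", h)
  cached <- memoN[[key]]
  if (!is.null(cached) && (attr(cached, "cap") >= cap ||
                           attr(cached, "complete")))
    return(cached[seq_len(min(length(cached), cap))])
  sidx <- eng$sidx; hidx <- eng$hidx; costs <- eng$costs
  target <- eng$C[p, h]
  if (!is.finite(target)) return(list())
  if (p <= sidx$ntip) {
    res <- list(btNode(eng, p, h))
  } else {
    kids <- sidx$children[[p]]
    q1 <- kids[1]; q2 <- kids[2]
    d1 <- eng$DOWN[q1, ]; d2 <- eng$DOWN[q2, ]
    o1 <- eng$OUT[[q1]]; o2 <- eng$OUT[[q2]]
    res <- list()
    room <- function() cap - length(res)
    hk <- hidx$children[[h]]
    if (length(hk) == 2L) {
      for (orient in list(hk, rev(hk))) {
        if (room() <= 0L) break
        if (costs@tracking + d1[orient[1]] + d2[orient[2]] >
              target + RECTOL) next
        A <- enumDown(eng, q1, orient[1], room(), memoN, memoD)
        B <- enumDown(eng, q2, orient[2], room(), memoN, memoD)
        res <- c(res, crossMerge(A, B, room(), post = function(s) {
          s <- bumpCounts(s, cosp = 1L)
          addRow(s, list(sym = p, event = "cospeciation", hostPos = h,
                         target = NA_integer_, losses = NA_integer_))
        }))
      }
    }
    if (room() > 0L &&
        costs@duplication + d1[h] + d2[h] <= target + RECTOL) {
      A <- enumDown(eng, q1, h, room(), memoN, memoD)
      B <- enumDown(eng, q2, h, room(), memoN, memoD)
      res <- c(res, crossMerge(A, B, room(), post = function(s) {
        s <- bumpCounts(s, dup = 1L)
        addRow(s, list(sym = p, event = "duplication", hostPos = h,
                       target = NA_integer_, losses = NA_integer_))
      }))
    }
    for (jump in 1:2) {
      if (room() <= 0L) break
      stay <- if (jump == 1L) q2 else q1
      jq <- if (jump == 1L) q1 else q2
      dstay <- if (jump == 1L) d2[h] else d1[h]
      oj <- if (jump == 1L) o1[h] else o2[h]
      if (costs@switch + dstay + oj > target + RECTOL) next
      lands <- eng$canon[eng$allowed[h, eng$canon] &
                           eng$C[jq, eng$canon] <= oj + RECTOL]
      for (land in lands) {
        if (room() <= 0L) break
        A <- enumDown(eng, stay, h, room(), memoN, memoD)
        B <- enumNode(eng, jq, land, room(), memoN, memoD)
        res <- c(res, crossMerge(A, B, room(), post = function(s) {
          s <- bumpCounts(s, sw = 1L)
          addRow(s, list(sym = p, event = "switch", hostPos = h,
                         target = land, losses = NA_integer_))
        }))
      }
    }
  }
  attr(res, "cap") <- cap
  attr(res, "complete") <- length(res) < cap
  memoN[[key]] <- res
  res
}

# all optimal ways for p to enter the subtree at v and descend; each
# solution's loss count already includes the crossings
enumDown <- function(eng, p, v, cap, memoN, memoD) {
  if (cap <= 0L) return(list())
  key <- paste0(p, ".", v)
  cached <- memoD[[key]]
  if (!is.null(cached) && (attr(cached, "cap") >= cap ||
                           attr(cached, "complete")))
    return(cached[seq_len(min(length(cached), cap))])
  res <- list()
  if (eng$C[p, v] <= eng$DOWN[p, v] + RECTOL)
    res <- enumNode(eng, p, v, cap, memoN, memoD)
  kids <- eng$hidx$children[[v]]
  kids <- kids[order(match(kids, eng$canon))]
  for (k in kids) {
    if (length(res) >= cap) break
    if (eng$DOWN[p, k] + eng$costs@loss > eng$DOWN[p, v] + RECTOL) next
    sub <- enumDown(eng, p, k, cap - length(res), memoN, memoD)
    res <- c(res, lapply(sub, function(s) bumpCounts(s, loss = 1L)))
  }
  attr(res, "cap") <- cap
  attr(res, "complete") <- length(res) < cap
  memoD[[key]] <- res
  res
}

## ---- assembling the S4 result ------------------------------------------

makeReconciliation <- function(tg, costs, sol, eng) {
  hidx <- eng$hidx; sidx <- eng$sidx
  rows <- sol$rows
  df <- data.frame(
    symbiont = vapply(rows, function(r)
      symbiontNodeLabel(sidx, tg@symbiont$tip.label, r$sym), character(1)),
    event = vapply(rows, function(r) r$event, character(1)),
    hostPosition = vapply(rows, function(r)
      hostPositionLabel(hidx, tg@host$tip.label, r$hostPos), character(1)),
    switchTarget = vapply(rows, function(r)
      if (is.na(r$target)) NA_character_ else
        hostPositionLabel(hidx, tg@host$tip.label, r$target), character(1)),
    losses = vapply(rows, function(r) as.integer(r$losses), integer(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$symbiont), , drop = FALSE]
  rownames(df) <- NULL
  cnt <- eventCounts(cospeciations = sol$counts[["cosp"]],
                     duplications = sol$counts[["dup"]],
                     switches = sol$counts[["sw"]],
                     losses = sol$counts[["loss"]],
                     ftd = sol$counts[["ftd"]])
  new("Reconciliation", tanglegram = tg, costs = costs, counts = cnt,
      totalCost = solCost(sol, costs), placements = df)
}

singleTipReconciliation <- function(tg, costs) {
  host <- tg@host
  hidx <- treeIndex(host)
  hids <- match(tg@assoc[[1]], host$tip.label)
  lab <- tg@symbiont$tip.label[1]
  if (length(hids) == 1L) {
    cnt <- eventCounts()
    df <- data.frame(symbiont = lab, event = "tip",
                     hostPosition = host$tip.label[hids],
                     switchTarget = NA_character_, losses = 0L,
                     stringsAsFactors = FALSE)
    tc <- 0
  } else {
    D <- subtreeMatrix(hidx)
    sp <- spanningInfo(hidx, D, hids)
    cnt <- eventCounts(ftd = sp$nftd, losses = sp$nleave)
    df <- data.frame(symbiont = lab, event = "widespread",
                     hostPosition = hostPositionLabel(hidx, host$tip.label,
                                                      sp$mrca),
                     switchTarget = NA_character_, losses = sp$nleave,
                     stringsAsFactors = FALSE)
    tc <- sp$nftd * costs@ftd + sp$nleave * costs@loss
  }
  new("Reconciliation", tanglegram = tg, costs = costs, counts = cnt,
      totalCost = tc, placements = df)
}
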