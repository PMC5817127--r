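#' Simulate an ultrametric Yule host tree
#'
#' Pure-birth simulation with unit birth rate: starting from the root
#' split (two lineages at time 0), each of the k extant lineages waits an
#' Exp(k) time to the next split; after the n-th lineage appears the
#' process is held a final Exp(n) interval and all tips are cut at that
#' time, so the expected tree height is sum_{k=2..n} 1/k. Tips are
#' labelled h1..hn in serialization order.
#'
#' @param nTips number of tips (>= 2)
#' @param seed integer seed
#' @return an ultrametric `phylo` tree with branch lengths
#' @examples
#' simulateHostTree(8, seed = 1)
#' @export
simulateHostTree <- function(nTips, seed = 1L) {
  if (nTips < 2L) stop("nTips must be >= 2")
  set.seed(as.integer(seed))
  nodeTime <- 0            # internal node birth times; node 1 = root
  nodeParent <- NA_integer_
  lineageParent <- c(1L, 1L)  # each extant lineage hangs from a node
  t <- 0
  k <- 2L
  while (k < nTips) {
    t <- t + stats::rexp(1L, rate = k)
    i <- sample.int(k, 1L)
    nodeTime <- c(nodeTime, t)
    nodeParent <- c(nodeParent, lineageParent[i])
    newNode <- length(nodeTime)
    lineageParent[i] <- newNode
    lineageParent <- c(lineageParent, newNode)
    k <- k + 1L
  }
  tEnd <- t + stats::rexp(1L, rate = k)
  nodeKids <- lapply(seq_along(nodeTime), function(v)
    which(nodeParent == v))
  tipKids <- lapply(seq_along(nodeTime), function(v)
    which(lineageParent == v))
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  nwk <- function(v) {
    parts <- character(0)
    for (w in nodeKids[[v]])
      parts <- c(parts, paste0(nwk(w), ":", fmt(nodeTime[w] - nodeTime[v])))
    for (dummy in tipKids[[v]]) {
      counter$i <- counter$i + 1L
      parts <- c(parts, paste0("h", counter$i, ":",
                               fmt(tEnd - nodeTime[v])))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  parseNewick(paste0(nwk(1L), ";"))
}

#' Joint host-symbiont cophylogeny simulator with a known event ledger
#'
#' Simulates a symbiont tree down an ultrametric host tree under the
#' generative converse of the five-event reconciliation model. One
#' symbiont lineage starts at the host root. At each host speciation a
#' resident lineage cospeciates with probability `pCospeciation`
#' (recording a cospeciation), otherwise follows one uniformly chosen
#' daughter (recording a loss on the missed side) — except on a host
#' cherry, where with probability `pFtdCherry` it instead becomes a single
#' widespread tip spanning both tips (recording one failure to diverge).
#' Along host edges, host switches and duplications arrive as Poisson
#' processes with the given per-unit-time rates; a switch sends one
#' daughter to a uniformly chosen contemporaneous host edge (excluding the
#' current one), recording the event. Because the simulator has true event
#' times, switch recipients are always time-consistent even though the
#' solver in [reconcile()] is untimed.
#'
#' @param host ultrametric `phylo` host tree with branch lengths
#' @param pCospeciation probability a resident lineage cospeciates at a
#'   host speciation
#' @param switchRate host-switch rate per unit branch length per lineage
#' @param duplicationRate duplication rate per unit branch length per
#'   lineage
#' @param pFtdCherry probability of failure to diverge on a host cherry
#' @param seed integer seed
#' @return a [CophyloSim-class]: the simulated [Tanglegram-class] plus the
#'   true [EventCounts-class] and an event ledger
#' @examples
#' h <- simulateHostTree(8, seed = 2)
#' simulateCophylogeny(h, pCospeciation = 1, switchRate = 0,
#'                     duplicationRate = 0, pFtdCherry = 0, seed = 3)
#' @export
simulateCophylogeny <- function(host, pCospeciation = 0.8,
                                switchRate = 0.5, duplicationRate = 0,
                                pFtdCherry = 0, seed = 1L) {
  stopifnot(inherits(host, "phylo"))
  if (is.null(host$edge.length)) stop("host tree must have branch lengths")
  stopifnot(pCospeciation >= 0, pCospeciation <= 1,
            pFtdCherry >= 0, pFtdCherry <= 1,
            switchRate >= 0, duplicationRate >= 0)
  if (!isBinaryTree(host)) stop("host tree must be binary")
  set.seed(as.integer(seed))
  hidx <- treeIndex(host)
  ntip <- hidx$ntip
  nodeTime <- ape::node.depth.edgelength(host)  # absolute times
  ledger <- list()
  counts <- c(cosp = 0L, dup = 0L, sw = 0L, loss = 0L, ftd = 0L)
  note <- function(event, h, t) {
    counts[[event]] <<- counts[[event]] + 1L
    ledger[[length(ledger) + 1L]] <<- list(
      event = event,
      hostPosition = hostPositionLabel(hidx, host$tip.label, h),
      time = t)
  }
  # edges identified by their lower node; edge above node v spans
  # (nodeTime[parent], nodeTime[v]); alive at time t if it covers t
  aliveAt <- function(t, exclude) {
    v <- which(!is.na(hidx$parent) &
                 nodeTime[hidx$parent] <= t & t < nodeTime)
    setdiff(v, exclude)
  }
  isCherry <- function(v) {
    kids <- hidx$children[[v]]
    length(kids) == 2L && all(kids <= ntip)
  }
  tipCount <- new.env(parent = emptyenv()); tipCount$i <- 0L
  # returns a nested list describing the symbiont subtree of one lineage
  # sitting on the host edge above `v` at time `t`
  simLineage <- function(v, t) {
    tEdge <- nodeTime[v]
    repeat {
      dSwitch <- if (switchRate > 0) stats::rexp(1L, switchRate) else Inf
      dDup <- if (duplicationRate > 0) stats::rexp(1L, duplicationRate)
              else Inf
      if (t + min(dSwitch, dDup) < tEdge) {
        tEv <- t + min(dSwitch, dDup)
        if (dSwitch <= dDup) {
          cand <- aliveAt(tEv, exclude = v)
          if (length(cand) == 0L) { t <- tEv; next }  # nowhere to go
          recip <- cand[sample.int(length(cand), 1L)]
          note("sw", v, tEv)
          stay <- simLineage(v, tEv)
          jump <- simLineage(recip, tEv)
          return(list(kind = "node", t = tEv, kids = list(stay, jump)))
        }
        note("dup", v, tEv)
        a <- simLineage(v, tEv)
        b <- simLineage(v, tEv)
        return(list(kind = "node", t = tEv, kids = list(a, b)))
      }
      break
    }
    # reached the bottom of the host edge
    if (v <= ntip) {
      tipCount$i <- tipCount$i + 1L
      return(list(kind = "tip", t = tEdge,
                  label = paste0("s", tipCount$i),
                  hosts = host$tip.label[v]))
    }
    kids <- hidx$children[[v]]
    if (isCherry(v) && stats::runif(1L) < pFtdCherry) {
      note("ftd", v, tEdge)
      tipCount$i <- tipCount$i + 1L
      # widespread tip: persists on both daughters without speciating
      return(list(kind = "tip", t = max(nodeTime[kids]),
                  label = paste0("s", tipCount$i),
                  hosts = host$tip.label[kids]))
    }
    if (stats::runif(1L) < pCospeciation) {
      note("cosp", v, tEdge)
      a <- simLineage(kids[1], tEdge)
      b <- simLineage(kids[2], tEdge)
      return(list(kind = "node", t = tEdge, kids = list(a, b)))
    }
    follow <- kids[sample.int(2L, 1L)]
    note("loss", v, tEdge)
    simLineage(follow, tEdge)
  }
  sim <- simLineage(hidx$root, nodeTime[hidx$root])

  assoc <- list()
  fmt <- function(x) format(max(x, 0), digits = 12, scientific = FALSE,
                            trim = TRUE)
  nwk <- function(x, t0) {
    if (x$kind == "tip") {
      assoc[[x$label]] <<- x$hosts
      paste0(x$label, ":", fmt(x$t - t0))
    } else {
      paste0("(", nwk(x$kids[[1]], x$t), ",", nwk(x$kids[[2]], x$t), "):",
             fmt(x$t - t0))
    }
  }
  symbiont <- if (sim$kind == "tip") {
    # degenerate single-lineage outcome: one tip, no branching event
    assoc[[sim$label]] <- sim$hosts
    parseNewick(paste0("(", sim$label, ");"))
  } else {
    parseNewick(paste0(nwk(sim, nodeTime[hidx$root]), ";"))
  }
  ledgerDf <- if (length(ledger)) data.frame(
    event = vapply(ledger, `[[`, character(1), "event"),
    hostPosition = vapply(ledger, `[[`, character(1), "hostPosition"),
    time = vapply(ledger, `[[`, numeric(1), "time"),
    stringsAsFactors = FALSE) else
    data.frame(event = character(0), hostPosition = character(0),
               time = numeric(0))
  new("CophyloSim",
      tanglegram = tanglegram(host, symbiont, assoc),
      counts = eventCounts(cospeciations = counts[["cosp"]],
                           duplications = counts[["dup"]],
                           switches = counts[["sw"]],
                           losses = counts[["loss"]],
                           ftd = counts[["ftd"]]),
      ledger = ledgerDf)
}

#' Simulate a clade-rank table with known regression structure
#'
#' Generates records from exactly the model fitted by
#' [fitPoissonPGLMM()]: `y_i ~ Poisson(exp(beta0 + beta1 * x_i +
#' a_host(i) + g_genus(i) + e_i))` with `a ~ N(0, vPhylo * C)` (C the
#' phylogenetic correlation of the host tree under Grafen lengths),
#' `g ~ N(0, vGenus * I)` and observation-level `e_i ~ N(0, vResid)`.
#' Host clade ranks are computed from the host tree; genus labels are
#' assigned by host subtree blocks (the clades hanging two splits below
#' the root, so related hosts share a genus).
#'
#' @param host rooted binary `phylo` host tree
#' @param beta0,beta1 intercept and host-clade-rank coefficient on the log
#'   scale
#' @param vPhylo,vGenus,vResid variance components (>= 0)
#' @param nPerHost records generated per host tip
#' @param seed integer seed
#' @return a data.frame with columns `symbiont`, `symbiont_rank` (response
#'   y), `host`, `host_rank` (covariate x) and `genus`
#' @export
simulateCladeRankTable <- function(host, beta0 = 1, beta1 = 0.5,
                                   vPhylo = 0.3, vGenus = 0.1,
                                   vResid = 0.1, nPerHost = 5L,
                                   seed = 1L) {
  stopifnot(vPhylo >= 0, vGenus >= 0, vResid >= 0, nPerHost >= 1L)
  set.seed(as.integer(seed))
  hidx <- treeIndex(host)
  tips <- host$tip.label
  ranks <- cladeRank(host, tips)
  genus <- genusBlocks(host)
  C <- phyloCorrelation(host, lengths = "grafen")
  q <- length(tips)
  a <- if (vPhylo > 0) {
    L <- chol(C[tips, tips])
    as.numeric(crossprod(L, stats::rnorm(q)) * sqrt(vPhylo))
  } else rep(0, q)
  names(a) <- tips
  glev <- unique(genus)
  g <- if (vGenus > 0) stats::rnorm(length(glev), 0, sqrt(vGenus)) else
    rep(0, length(glev))
  names(g) <- glev
  hostCol <- rep(tips, each = nPerHost)
  n <- length(hostCol)
  e <- if (vResid > 0) stats::rnorm(n, 0, sqrt(vResid)) else rep(0, n)
  eta <- beta0 + beta1 * ranks[match(hostCol, tips)] + a[hostCol] +
    g[genus[match(hostCol, tips)]] + e
  y <- stats::rpois(n, exp(eta))
  data.frame(symbiont = paste0("obs", seq_len(n)),
             symbiont_rank = y,
             host = hostCol,
             host_rank = ranks[match(hostCol, tips)],
             genus = genus[match(hostCol, tips)],
             stringsAsFactors = FALSE)
}

# genus labels by host subtree blocks: the clades hanging three splits
# below the root; shallower tips form their own block. Depth 3 keeps
# blocks small (a few congeneric hosts each), matching the genus-to-host
# ratio of real association tables.
genusBlocks <- function(host, depth = 3L) {
  hidx <- treeIndex(host)
  tips <- host$tip.label
  block <- integer(hidx$ntip)
  D <- subtreeMatrix(hidx)
  anchors <- c(which(hidx$depth == depth),
               which(seq_len(hidx$n) <= hidx$ntip & hidx$depth < depth))
  anchors <- anchors[order(hidx$minTip[anchors], method = "radix")]
  for (i in seq_along(anchors))
    block[which(D[anchors[i], seq_len(hidx$ntip)])] <- i
  paste0("g", block)
}
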