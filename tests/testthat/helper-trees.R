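# Random tree / tanglegram generators shared across the test files.
# Trees are built by random sequential joins, so every labelled binary
# topology has positive probability.

randomBinaryTree <- function(n, prefix = "t", lengths = FALSE) {
  labs <- paste0(prefix, seq_len(n))
  nodes <- as.list(labs)
  if (lengths)
    nodes <- lapply(nodes, function(x)
      paste0(x, ":", signif(stats::runif(1, 0.1, 2), 4)))
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    joined <- paste0("(", nodes[[i[1]]], ",", nodes[[i[2]]], ")")
    if (lengths)
      joined <- paste0(joined, ":", signif(stats::runif(1, 0.1, 2), 4))
    nodes[[i[1]]] <- joined
    nodes[[i[2]]] <- NULL
  }
  parseNewick(paste0(nodes[[1]], ";"))
}

randomTanglegram <- function(nHost, nSym, widespread = FALSE) {
  h <- randomBinaryTree(nHost, "h")
  s <- randomBinaryTree(nSym, "p")
  assoc <- lapply(seq_len(nSym), function(i) {
    k <- if (widespread) sample(1:2, 1L) else 1L
    sample(h$tip.label, k)
  })
  names(assoc) <- s$tip.label
  tanglegram(h, s, assoc)
}

randomCosts <- function(maxCost = 3L) {
  eventCosts(tracking = sample(0:maxCost, 1L),
             duplication = sample(0:maxCost, 1L),
             switch = sample(0:maxCost, 1L),
             loss = sample(0:maxCost, 1L),
             ftd = sample(0:maxCost, 1L))
}
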