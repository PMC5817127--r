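#' Parse a rooted tree from a newick string
#'
#' Thin validating wrapper around [ape::read.tree()]. The string must be a
#' single rooted newick statement terminated by ";". Labels and branch
#' lengths are preserved exactly; underscores in labels are preserved by
#' default, and single-quoted labels are unquoted (with
#' `underscores = "space"`, unquoted underscores are converted to spaces,
#' the classic newick convention).
#'
#' @param text a newick string
#' @param underscores "preserve" (default) or "space"
#' @return an object of class `ape::phylo`
#' @examples
#' tr <- parseNewick("((A,B),C);")
#' ape::Ntip(tr)
#' @export
parseNewick <- function(text, underscores = c("preserve", "space")) {
  underscores <- match.arg(underscores)
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  # locate structural errors before handing off, so the message can name
  # the offending position
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  inq <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") inq <- !inq
    if (inq) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at position ", i)
    }
  }
  if (inq) stop("newick parse error: unterminated quoted label")
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' (missing ')' before ",
         "position ", length(chars), ")")
  if (!endsWith(text, ";"))
    stop("newick parse error: statement must end with ';' (position ",
         length(chars), ")")
  phy <- ape::read.tree(text = text)
  if (is.null(phy))
    stop("newick parse error: ape could not interpret the statement")
  # unquote quoted labels; normalise underscores if asked
  unq <- function(x) {
    quoted <- grepl("^'.*'$", x)
    x[quoted] <- gsub("^'|'$", "", x[quoted])
    if (underscores == "space") x[!quoted] <- gsub("_", " ", x[!quoted])
    x
  }
  phy$tip.label <- unq(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unq(phy$node.label)
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("newick parse error: duplicate tip label(s): ",
         paste(dup, collapse = ", "))
  }
  if (any(!nzchar(phy$tip.label)))
    stop("newick parse error: empty tip label")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("newick parse error: negative branch length (",
         min(phy$edge.length), ")")
  phy
}

#' Write a tree as a newick string
#'
#' With `canonical = TRUE` the children of every node are ordered by their
#' lexicographically smallest descendant tip label, so that topologically
#' identical trees serialize to bit-identical strings.
#'
#' @param tree a `phylo` tree
#' @param canonical order children deterministically? (default `FALSE`:
#'   child order as stored)
#' @return a single newick string terminated by ";"
#' @examples
#' writeNewick(parseNewick("((B,A),C);"), canonical = TRUE)
#' @export
writeNewick <- function(tree, canonical = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!canonical)
    return(ape::write.tree(tree))
  idx <- treeIndex(tree)
  lens <- tree$edge.length
  fmt <- function(x) {
    # shortest decimal representation that round-trips
    s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
    sub("0+$", "", sub("\\.$", "", s))
  }
  rec <- function(node) {
    kids <- idx$children[[node]]
    lab <- if (node <= idx$ntip) tree$tip.label[node] else ""
    body <- if (length(kids)) {
      parts <- vapply(kids, rec, character(1))
      ord <- order(idx$minTip[kids], method = "radix")
      paste0("(", paste(parts[ord], collapse = ","), ")", lab)
    } else lab
    if (!is.null(lens) && node != idx$root) {
      ei <- idx$edgeOf[node]
      body <- paste0(body, ":", fmt(lens[ei]))
    }
    body
  }
  paste0(rec(idx$root), ";")
}

#' Clade rank of a tip
#'
#' The number of speciation events (internal nodes) between the root of a
#' binary tree and a given tip: the path from the root (inclusive) to the
#' tip (exclusive), i.e. the tip's topological depth in edges. A
#' topology-only proxy for relative taxon age: in a two-tip tree both tips
#' have rank 1.
#'
#' @param tree a rooted binary `phylo` tree
#' @param taxon a tip label (vectorised)
#' @return integer vector of clade ranks
#' @examples
#' cladeRank(parseNewick("((A,B),(C,(D,E)));"), c("A", "D"))
#' @export
cladeRank <- function(tree, taxon) {
  stopifnot(inherits(tree, "phylo"))
  if (!isBinaryTree(tree))
    stop("clade ranks are defined on rooted binary trees")
  i <- match(taxon, tree$tip.label)
  if (anyNA(i))
    stop("unknown taxon: ", paste(taxon[is.na(i)], collapse = ", "))
  idx <- treeIndex(tree)
  idx$depth[i]
}

## ---- internal tree machinery ------------------------------------------

# parent/children/depth/subtree tables for a phylo object; node ids are
# ape ids (tips 1..ntip, internals ntip+1..).
treeIndex <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  parent <- integer(n); parent[] <- NA_integer_
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  edgeOf <- integer(n); edgeOf[] <- NA_integer_
  edgeOf[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  children <- lapply(seq_len(n), function(i) phy$edge[phy$edge[, 1] == i, 2])
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  if (length(root) != 1L) {
    if (ntip == 1L && nnode >= 1L) root <- ntip + 1L else
      stop("tree must have exactly one root")
  }
  depth <- integer(n)
  minTip <- character(n)
  # preorder for depth, postorder for minTip
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    stack <- c(stack, children[[v]])
  }
  for (v in ord) depth[v] <- if (v == root) 0L else depth[parent[v]] + 1L
  for (v in rev(ord)) {
    minTip[v] <- if (v <= ntip) phy$tip.label[v] else
      min(minTip[children[[v]]])
  }
  list(ntip = ntip, n = n, root = root, parent = parent,
       children = children, depth = depth, minTip = minTip,
       edgeOf = edgeOf, preorder = ord)
}

# TRUE if the tree is rooted with every internal node binary (exactly two
# children); a 1-tip tree is vacuously binary.
isBinaryTree <- function(phy) {
  if (!inherits(phy, "phylo")) return(FALSE)
  ntip <- length(phy$tip.label)
  if (ntip == 1L) return(TRUE)
  if (is.null(phy$edge) || !nrow(phy$edge)) return(FALSE)
  deg <- tabulate(phy$edge[, 1], nbins = ntip + phy$Nnode)
  internal <- deg > 0L
  all(deg[internal] == 2L)
}

# descendant-or-self logical matrix D[i, j]: j lies in the subtree of i
subtreeMatrix <- function(idx) {
  n <- idx$n
  D <- matrix(FALSE, n, n)
  for (v in rev(idx$preorder)) {
    D[v, v] <- TRUE
    for (k in idx$children[[v]]) D[v, ] <- D[v, ] | D[k, ]
  }
  D
}

# deterministic ordering of host positions: by smallest descendant tip
# label, ancestors before descendants
canonicalNodeOrder <- function(idx) {
  order(idx$minTip, idx$depth, method = "radix")
}
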