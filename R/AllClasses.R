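#' @import methods
NULL

setOldClass("phylo")

#' Event-cost vector for the five-event reconciliation model
#'
#' Holds the per-event costs (dimensionless units) used to score a
#' reconciliation: cospeciation ("phylogenetic tracking"), duplication,
#' host switch, loss (sorting event), and failure to diverge.
#'
#' @slot tracking cost of a cospeciation event
#' @slot duplication cost of a duplication event
#' @slot switch cost of a host-switch event
#' @slot loss cost of a loss (sorting) event
#' @slot ftd cost of a failure-to-diverge event
#' @seealso [eventCosts()], [reconcile()]
#' @export
setClass("EventCosts",
  representation(tracking = "numeric", duplication = "numeric",
                 switch = "numeric", loss = "numeric", ftd = "numeric"))

setValidity("EventCosts", function(object) {
  v <- c(object@tracking, object@duplication, object@switch,
         object@loss, object@ftd)
  if (length(v) != 5L || anyNA(v) || any(!is.finite(v)))
    return("all five event costs must be finite non-missing scalars")
  if (any(v < 0)) return("event costs must be non-negative")
  TRUE
})

#' Event counts of a reconciliation
#'
#' @slot cospeciations number of cospeciation events
#' @slot duplications number of duplication events
#' @slot switches number of host-switch events
#' @slot losses number of loss events
#' @slot ftd number of failure-to-diverge events
#' @export
setClass("EventCounts",
  representation(cospeciations = "integer", duplications = "integer",
                 switches = "integer", losses = "integer", ftd = "integer"))

setValidity("EventCounts", function(object) {
  v <- c(object@cospeciations, object@duplications, object@switches,
         object@losses, object@ftd)
  if (length(v) != 5L || anyNA(v)) return("all five counts must be scalars")
  if (any(v < 0L)) return("event counts must be non-negative")
  TRUE
})

#' Tanglegram: a host tree, a symbiont tree and their tip associations
#'
#' The input object of the reconciliation and permutation analyses. Both
#' trees must be rooted and binary (every internal node has exactly two
#' children; a single-tip tree is accepted as a degenerate case). Every
#' symbiont tip must be associated with a non-empty set of host tips; a tip
#' mapped to two or more hosts is "widespread" and is scored by the
#' failure-to-diverge rule.
#'
#' @slot host rooted binary host tree (`ape::phylo`)
#' @slot symbiont rooted binary symbiont tree (`ape::phylo`)
#' @slot assoc named list; names are symbiont tip labels, each element a
#'   character vector of host tip labels
#' @seealso [tanglegram()], [buildTanglegram()], [reconcile()]
#' @export
setClass("Tanglegram",
  representation(host = "phylo", symbiont = "phylo", assoc = "list"))

setValidity("Tanglegram", function(object) {
  ht <- object@host; st <- object@symbiont; assoc <- object@assoc
  msg <- character()
  if (!isBinaryTree(ht)) msg <- c(msg, "host tree is not rooted binary")
  if (!isBinaryTree(st)) msg <- c(msg, "symbiont tree is not rooted binary")
  stips <- st$tip.label
  if (!setequal(names(assoc), stips) || anyDuplicated(names(assoc)))
    msg <- c(msg, "assoc names must be exactly the symbiont tip labels")
  hosts <- unlist(assoc, use.names = FALSE)
  if (any(lengths(assoc) == 0L))
    msg <- c(msg, "every symbiont tip needs a non-empty host set")
  bad <- setdiff(hosts, ht$tip.label)
  if (length(bad))
    msg <- c(msg, paste0("associated host(s) not in host tree: ",
                         paste(unique(bad), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A minimum-cost embedding of a symbiont tree into a host tree
#'
#' @slot tanglegram the input [Tanglegram-class]
#' @slot costs the [EventCosts-class] used for scoring
#' @slot counts the [EventCounts-class] of the reconstruction
#' @slot totalCost total cost (dot product of counts and costs)
#' @slot placements data.frame with one row per symbiont node: columns
#'   `symbiont` (node label or tip name), `event`
#'   (cospeciation/duplication/switch/tip/widespread), `hostPosition`
#'   (host node the symbiont node sits on, i.e. the lower node of the host
#'   edge), `switchTarget` (landing host position for switches, else NA),
#'   and `losses` (loss events charged below this node's event, on the
#'   descent paths of its children)
#' @export
setClass("Reconciliation",
  representation(tanglegram = "Tanglegram", costs = "EventCosts",
                 counts = "EventCounts", totalCost = "numeric",
                 placements = "data.frame"))

setValidity("Reconciliation", function(object) {
  cst <- object@costs; cnt <- object@counts
  expect <- sum(c(cnt@cospeciations, cnt@duplications, cnt@switches,
                  cnt@losses, cnt@ftd) *
                c(cst@tracking, cst@duplication, cst@switch,
                  cst@loss, cst@ftd))
  if (abs(expect - object@totalCost) > 1e-9)
    return("totalCost must equal the dot product of counts and costs")
  TRUE
})

#' Result of a random-tip-mapping permutation test
#'
#' @slot observedCost reconciliation cost of the observed tanglegram
#' @slot nullCosts costs under randomized tip mappings
#' @slot nPermutations number of randomizations (Monte-Carlo mode)
#' @slot pValue one-sided p-value (lower cost = better than random)
#' @slot mode "monte_carlo" or "exhaustive"
#' @slot seed RNG seed used (NA for exhaustive mode)
#' @export
setClass("PermutationResult",
  representation(observedCost = "numeric", nullCosts = "numeric",
                 nPermutations = "integer", pValue = "numeric",
                 mode = "character", seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (!object@mode %in% c("monte_carlo", "exhaustive"))
    return("mode must be monte_carlo or exhaustive")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p-value must lie in (0, 1]")
  TRUE
})

#' Posterior of the clade-rank Poisson phylogenetic GLMM
#'
#' @slot samples list with one element per chain; each a numeric matrix of
#'   thinned post-burn-in samples (columns `beta0`, `beta1`, `vPhylo`,
#'   `vGenus`, `vResid`)
#' @slot summary data.frame of posterior means and 95% credible intervals
#'   per parameter (merged chains), including the two H2 variants
#' @slot psrf named numeric vector of Gelman-Rubin potential scale
#'   reduction factors
#' @slot settings list of chain settings, priors and the seed
#' @export
setClass("PhyloGLMMResult",
  representation(samples = "list", summary = "data.frame",
                 psrf = "numeric", settings = "list"))

setValidity("PhyloGLMMResult", function(object) {
  if (!length(object@samples)) return("no chains")
  cols <- c("beta0", "beta1", "vPhylo", "vGenus", "vResid")
  ok <- vapply(object@samples, function(m)
    is.matrix(m) && all(cols %in% colnames(m)), logical(1))
  if (!all(ok)) return("each chain must be a matrix with the model columns")
  TRUE
})

#' Joint host-symbiont simulation with its true event ledger
#'
#' @slot tanglegram the simulated [Tanglegram-class]
#' @slot counts true [EventCounts-class] of the generating process
#' @slot ledger data.frame of individual events (event, host position label,
#'   time)
#' @export
setClass("CophyloSim",
  representation(tanglegram = "Tanglegram", counts = "EventCounts",
                 ledger = "data.frame"))
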