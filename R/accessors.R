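#' Construct an event-cost vector
#'
#' Defaults reproduce the common reconciliation baseline: free
#' cospeciation, unit cost for duplication, host switch, loss and failure
#' to diverge.
#'
#' @param tracking cospeciation ("phylogenetic tracking") cost
#' @param duplication duplication cost
#' @param switch host-switch cost
#' @param loss loss (sorting) cost
#' @param ftd failure-to-diverge cost
#' @return an [EventCosts-class] object
#' @examples
#' eventCosts(tracking = 0, switch = 2)
#' @export
eventCosts <- function(tracking = 0, duplication = 1, switch = 1,
                       loss = 1, ftd = 1) {
  new("EventCosts", tracking = as.numeric(tracking),
      duplication = as.numeric(duplication), switch = as.numeric(switch),
      loss = as.numeric(loss), ftd = as.numeric(ftd))
}

#' @describeIn eventCosts the three cost schemes of the study design:
#'   tracking always free, host-shift cost 0, 1 or 2; duplication, loss and
#'   failure to diverge at the default unit cost, except that the
#'   zero-shift scheme also sets duplication to 0 (mirroring the limitation
#'   of the original software's zero-cost configuration).
#' @export
costSchemes <- function() {
  list("0,0" = eventCosts(tracking = 0, duplication = 0, switch = 0),
       "0,1" = eventCosts(tracking = 0, duplication = 1, switch = 1),
       "0,2" = eventCosts(tracking = 0, duplication = 1, switch = 2))
}

#' Construct an event-count vector
#' @param cospeciations,duplications,switches,losses,ftd non-negative counts
#' @return an [EventCounts-class] object
#' @export
eventCounts <- function(cospeciations = 0L, duplications = 0L,
                        switches = 0L, losses = 0L, ftd = 0L) {
  new("EventCounts", cospeciations = as.integer(cospeciations),
      duplications = as.integer(duplications),
      switches = as.integer(switches), losses = as.integer(losses),
      ftd = as.integer(ftd))
}

#' Host tree accessor
#' @param x a [Tanglegram-class] or [CophyloSim-class]
#' @return the host `phylo` tree
#' @export
setGeneric("hostTree", function(x) standardGeneric("hostTree"))
#' @rdname hostTree
setMethod("hostTree", "Tanglegram", function(x) x@host)
#' @rdname hostTree
setMethod("hostTree", "CophyloSim", function(x) x@tanglegram@host)

#' Symbiont tree accessor
#' @param x a [Tanglegram-class] or [CophyloSim-class]
#' @return the symbiont `phylo` tree
#' @export
setGeneric("symbiontTree", function(x) standardGeneric("symbiontTree"))
#' @rdname symbiontTree
setMethod("symbiontTree", "Tanglegram", function(x) x@symbiont)
#' @rdname symbiontTree
setMethod("symbiontTree", "CophyloSim", function(x) x@tanglegram@symbiont)

#' Tip association accessor
#' @param x a [Tanglegram-class]
#' @return named list: symbiont tip -> character vector of host tips
#' @export
setGeneric("associations", function(x) standardGeneric("associations"))
#' @rdname associations
setMethod("associations", "Tanglegram", function(x) x@assoc)

#' Total reconciliation cost accessor
#' @param x a [Reconciliation-class]
#' @return numeric total cost in cost units
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))
#' @rdname totalCost
setMethod("totalCost", "Reconciliation", function(x) x@totalCost)

#' Event-count accessor
#' @param x a [Reconciliation-class] or [CophyloSim-class]
#' @return the [EventCounts-class]
#' @export
setGeneric("getEventCounts", function(x) standardGeneric("getEventCounts"))
#' @rdname getEventCounts
setMethod("getEventCounts", "Reconciliation", function(x) x@counts)
#' @rdname getEventCounts
setMethod("getEventCounts", "CophyloSim", function(x) x@counts)

#' Permutation-test p-value accessor
#' @param x a [PermutationResult-class]
#' @return the one-sided p-value
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname pValue
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' Event counts as a named integer vector
#' @param x an [EventCounts-class]
#' @return named integer vector
#' @export
countsVector <- function(x) {
  stopifnot(is(x, "EventCounts"))
  c(cospeciations = x@cospeciations, duplications = x@duplications,
    switches = x@switches, losses = x@losses, ftd = x@ftd)
}

#' Event costs as a named numeric vector
#' @param x an [EventCosts-class]
#' @return named numeric vector
#' @export
costsVector <- function(x) {
  stopifnot(is(x, "EventCosts"))
  c(tracking = x@tracking, duplication = x@duplication,
    switch = x@switch, loss = x@loss, ftd = x@ftd)
}

## ---- show methods ------------------------------------------------------

setMethod("show", "EventCosts", function(object) {
  v <- costsVector(object)
  cat("EventCosts:", paste(names(v), v, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "EventCounts", function(object) {
  v <- countsVector(object)
  cat("EventCounts:", paste(names(v), v, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Tanglegram", function(object) {
  wide <- sum(lengths(object@assoc) > 1L)
  cat("Tanglegram:", length(object@host$tip.label), "host tips,",
      length(object@symbiont$tip.label), "symbiont tips",
      if (wide) paste0("(", wide, " widespread)") else "", "\n")
})

setMethod("show", "Reconciliation", function(object) {
  cat("Reconciliation, total cost", object@totalCost, "\n  ")
  show(object@counts)
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult (", object@mode, "): observed cost ",
      object@observedCost, ", ", length(object@nullCosts),
      " null costs, p = ", format(object@pValue, digits = 4), "\n",
      sep = "")
})

setMethod("show", "PhyloGLMMResult", function(object) {
  cat("PhyloGLMMResult:", length(object@samples), "chains,",
      nrow(object@samples[[1]]), "retained samples each\n")
  print(object@summary, digits = 3)
})

setMethod("show", "CophyloSim", function(object) {
  cat("CophyloSim with true ")
  show(object@counts)
  show(object@tanglegram)
})
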