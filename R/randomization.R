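#' Random tip mapping
#'
#' Returns a tanglegram identical to the input except that each symbiont
#' tip is independently reassigned to a single host tip drawn uniformly at
#' random — the classic randomization null for event-based cophylogenetic
#' analysis. Widespread tips collapse to one random host under the null.
#'
#' @param tg a [Tanglegram-class]
#' @param seed optional integer seed; if `NULL`, the current RNG state is
#'   used (and advanced)
#' @param model "uniform" (default; independent uniform reassignment of
#'   each tip, the documented behaviour of the classic software) or
#'   "permute_observed" (shuffle the observed host sets among the symbiont
#'   tips, preserving the observed host multiset)
#' @return a [Tanglegram-class] with randomized associations
#' @export
randomTipMapping <- function(tg, seed = NULL,
                             model = c("uniform", "permute_observed")) {
  model <- match.arg(model)
  stopifnot(is(tg, "Tanglegram"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  hosts <- tg@host$tip.label
  stips <- tg@symbiont$tip.label
  if (model == "uniform") {
    assoc <- lapply(seq_along(stips),
                    function(i) hosts[sample.int(length(hosts), 1L)])
  } else {
    assoc <- unname(tg@assoc[sample.int(length(stips))])
  }
  names(assoc) <- stips
  tanglegram(tg@host, tg@symbiont, assoc)
}

#' Permutation test of reconciliation cost against random tip mappings
#'
#' Tests whether the observed tanglegram reconciles more cheaply than
#' expected if symbiont tips were associated with hosts at random. The
#' test is one-sided: a null mapping counts as at least as extreme when
#' its optimal cost is less than or equal to the observed optimal cost
#' (lower cost = better fit).
#'
#' In `monte_carlo` mode, `p = (1 + #\{null <= observed\}) /
#' (nPermutations + 1)` (add-one smoothing guarantees p > 0). In
#' `exhaustive` mode all `(host tips)^(symbiont tips)` single-host
#' mappings are enumerated and `p = #\{mappings with cost <= observed\} /
#' (total mappings)`, the observed mapping counting among the enumerated
#' ones; exhaustive mode is refused above 10^6 mappings.
#'
#' @inheritParams reconcile
#' @param nPermutations number of random mappings (Monte-Carlo mode)
#' @param seed integer seed for reproducibility (Monte-Carlo mode)
#' @param mode "monte_carlo" or "exhaustive"
#' @return a [PermutationResult-class]
#' @examples
#' tg <- buildTanglegram(parseNewick("((h1,h2),h3);"),
#'                       parseNewick("((p1,p2),p3);"),
#'                       list(p1 = "h1", p2 = "h2", p3 = "h3"))
#' permutationTest(tg, eventCosts(), mode = "exhaustive")
#' @export
permutationTest <- function(tg, costs = eventCosts(),
                            nPermutations = 999L, seed = 1L,
                            mode = c("monte_carlo", "exhaustive"),
                            switchConstraint = c("incomparable",
                                                 "unconstrained")) {
  mode <- match.arg(mode)
  switchConstraint <- match.arg(switchConstraint)
  stopifnot(is(tg, "Tanglegram"), is(costs, "EventCosts"))
  observed <- totalCost(reconcile(tg, costs,
                                  switchConstraint = switchConstraint))
  hosts <- tg@host$tip.label
  stips <- tg@symbiont$tip.label
  solveMapped <- function(hostOf) {
    assoc <- as.list(hosts[hostOf])
    names(assoc) <- stips
    totalCost(reconcile(tanglegram(tg@host, tg@symbiont, assoc), costs,
                        switchConstraint = switchConstraint))
  }
  if (mode == "exhaustive") {
    total <- length(hosts)^length(stips)
    if (total > 1e6)
      stop("size error: exhaustive mode needs (host tips)^(symbiont tips)",
           " <= 1e6, got ", total)
    grid <- as.matrix(expand.grid(rep(list(seq_along(hosts)),
                                      length(stips)),
                                  KEEP.OUT.ATTRS = FALSE))
    nullCosts <- apply(grid, 1L, solveMapped)
    p <- sum(nullCosts <= observed + RECTOL) / total
    new("PermutationResult", observedCost = observed,
        nullCosts = as.numeric(nullCosts), nPermutations = as.integer(total),
        pValue = p, mode = "exhaustive", seed = NA_integer_)
  } else {
    stopifnot(nPermutations >= 1L)
    set.seed(as.integer(seed))
    nullCosts <- vapply(seq_len(nPermutations), function(i)
      solveMapped(sample.int(length(hosts), length(stips),
                             replace = TRUE)),
      numeric(1))
    p <- (1 + sum(nullCosts <= observed + RECTOL)) / (nPermutations + 1)
    new("PermutationResult", observedCost = observed,
        nullCosts = as.numeric(nullCosts),
        nPermutations = as.integer(nPermutations),
        pValue = p, mode = "monte_carlo", seed = as.integer(seed))
  }
}
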