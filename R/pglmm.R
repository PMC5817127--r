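#' Phylogenetic correlation matrix of a host tree
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j
#' divided by the maximum root-to-tip depth; the diagonal is exactly 1.
#' With `lengths = "grafen"` branch lengths are first assigned by Grafen's
#' method (node height = number of descendant tips - 1, normalized), which
#' turns a cladogram into a valid ultrametric correlation structure.
#'
#' @param host `phylo` tree with >= 2 tips
#' @param lengths "given" (use the tree's branch lengths; error if absent)
#'   or "grafen"
#' @return a positive semi-definite correlation matrix with dimnames equal
#'   to the tip labels
#' @examples
#' phyloCorrelation(parseNewick("((A:1,B:1):1,C:2);"), lengths = "given")
#' @export
phyloCorrelation <- function(host, lengths = c("given", "grafen")) {
  lengths <- match.arg(lengths)
  stopifnot(inherits(host, "phylo"), length(host$tip.label) >= 2L)
  if (lengths == "grafen") {
    host <- ape::compute.brlen(host, method = "Grafen")
  } else if (is.null(host$edge.length)) {
    stop("lengths = \"given\" requires a tree with branch lengths")
  }
  V <- ape::vcv.phylo(host)
  C <- V / max(diag(V))
  diag(C) <- 1
  C[host$tip.label, host$tip.label]
}

#' Prior specification for the clade-rank GLMM
#'
#' Variance components get scaled inverse-chi-squared priors with scale
#' `V` and degree of belief `nu` (equivalently inverse-gamma with shape
#' `nu/2` and rate `nu*V/2`, the parameterisation of the classic animal
#' model software); fixed effects get zero-mean Gaussian priors with
#' variance `fixedVar`. The defaults `V = 1`, `nu = 0.02` are the
#' weakly-informative standard for this model class; `fixedVar = 1e10` is
#' effectively flat.
#'
#' @param V prior scale of each variance component (> 0)
#' @param nu degree of belief (> 0)
#' @param fixedVar prior variance of the fixed effects
#' @return a list with class `priorSpec`
#' @export
priorSpec <- function(V = 1, nu = 0.02, fixedVar = 1e10) {
  stopifnot(V > 0, nu > 0, fixedVar > 0)
  structure(list(V = V, nu = nu, fixedVar = fixedVar),
            class = "priorSpec")
}

#' Fit the Poisson phylogenetic GLMM of symbiont on host clade rank
#'
#' Bayesian Poisson regression with log link of the symbiont clade rank
#' `y` on the host clade rank `x`, with a host-phylogeny-structured random
#' effect `a ~ N(0, vPhylo * C)`, a host-genus random effect
#' `g ~ N(0, vGenus * I)` and an observation-level (overdispersion)
#' residual `e_i ~ N(0, vResid)`:
#' `y_i ~ Poisson(exp(beta0 + beta1 x_i + a_host(i) + g_genus(i) + e_i))`.
#' Sampling is Metropolis-within-Gibbs (adaptive random-walk updates of
#' the fixed and latent effects during burn-in, frozen afterwards;
#' conjugate inverse-gamma updates of the variance components), run as
#' independent parallel chains for convergence diagnostics.
#'
#' With zero records the variance components are sampled from their
#' priors, which is useful for prior-predictive checks.
#'
#' @param records data.frame with columns `symbiont_rank` (non-negative
#'   integer response), `host` (taxon label indexed in `corr`), `host_rank`
#'   (covariate) and `genus`; see [simulateCladeRankTable()]
#' @param corr phylogenetic correlation matrix over host taxa (see
#'   [phyloCorrelation()]). Hosts sharing a taxon in `corr` (for example
#'   several congeners mapped to one order-level tip) simply share a level
#'   of the phylogenetic effect.
#' @param priors a [priorSpec()]
#' @param nChains number of chains (>= 2 for diagnostics)
#' @param nIter iterations per chain
#' @param burnin discarded initial iterations (< nIter)
#' @param thin thinning interval
#' @param seed integer seed; chain c uses seed + c - 1
#' @return a [PhyloGLMMResult-class]
#' @export
fitPoissonPGLMM <- function(records, corr, priors = priorSpec(),
                            nChains = 3L, nIter = 1e5L, burnin = 2e4L,
                            thin = 50L, seed = 1L) {
  stopifnot(inherits(priors, "priorSpec"), nChains >= 1L, thin >= 1L)
  if (burnin >= nIter)
    stop("configuration error: burnin must be smaller than nIter")
  if (nrow(corr) != ncol(corr) || is.null(rownames(corr)))
    stop("corr must be a square matrix with taxon dimnames")
  n <- if (is.null(records)) 0L else nrow(records)
  if (n > 0L) {
    need <- c("symbiont_rank", "host", "host_rank", "genus")
    miss <- setdiff(need, names(records))
    if (length(miss))
      stop("records missing column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(records$host), rownames(corr))
    if (length(bad))
      stop("index error: host taxa absent from corr: ",
           paste(bad, collapse = ", "))
    y <- as.numeric(records$symbiont_rank)
    x <- as.numeric(records$host_rank)
    hostIdx <- match(records$host, rownames(corr))
    glev <- sort(unique(as.character(records$genus)))
    genusIdx <- match(as.character(records$genus), glev)
  } else {
    y <- x <- numeric(0)
    hostIdx <- genusIdx <- integer(0)
    glev <- character(0)
  }
  if (n > 0L) {
    Cinv <- tryCatch(solve(corr), error = function(e)
      stop("corr is singular; the phylogenetic effect needs a positive ",
           "definite correlation (did you duplicate taxa instead of ",
           "mapping hosts to shared taxa?)"))
    q <- nrow(corr)
  } else {
    # prior-only run: variance components are drawn from their priors
    Cinv <- matrix(numeric(0), 0L, 0L)
    q <- 0L
  }
  chains <- vector("list", nChains)
  for (ch in seq_len(nChains)) {
    set.seed(as.integer(seed) + ch - 1L)
    raw <- pglmm_mcmc(y, x, hostIdx - 1L, genusIdx - 1L,
                      as.integer(q), as.integer(length(glev)),
                      Cinv, priors$V, priors$nu, priors$fixedVar,
                      as.integer(nIter), as.integer(burnin),
                      as.integer(thin))
    colnames(raw) <- c("beta0", "beta1", "vPhylo", "vGenus", "vResid")
    chains[[ch]] <- raw
  }
  merged <- do.call(rbind, chains)
  h2all <- merged[, "vPhylo"] /
    (merged[, "vPhylo"] + merged[, "vGenus"] + merged[, "vResid"])
  h2nog <- merged[, "vPhylo"] / (merged[, "vPhylo"] + merged[, "vResid"])
  summ <- function(v) c(mean = mean(v),
                        lower95 = unname(stats::quantile(v, 0.025)),
                        upper95 = unname(stats::quantile(v, 0.975)))
  pars <- colnames(merged)
  tab <- t(vapply(pars, function(p) summ(merged[, p]), numeric(3)))
  tab <- rbind(tab, H2 = summ(h2all), H2_noGenus = summ(h2nog))
  psrf <- if (nChains >= 2L) gelmanRubin(chains) else
    stats::setNames(rep(NA_real_, length(pars)), pars)
  new("PhyloGLMMResult",
      samples = chains,
      summary = data.frame(parameter = rownames(tab), tab,
                           row.names = NULL),
      psrf = psrf,
      settings = list(priors = priors, nChains = nChains, nIter = nIter,
                      burnin = burnin, thin = thin, seed = seed,
                      n = n, taxa = rownames(corr), genera = glev))
}

#' Posterior summary of phylogenetic heritability
#'
#' H-squared is computed per posterior sample as
#' `vPhylo / (vPhylo + vGenus + vResid)` — the fraction of modeled
#' variance attributable to the phylogeny-structured effect, the analogue
#' of Pagel's lambda for this model. `denominator = "noGenus"` drops the
#' genus component from the denominator.
#'
#' @param result a [PhyloGLMMResult-class]
#' @param denominator "all" (default) or "noGenus"
#' @return a list with `mean`, `lower95`, `upper95` and the per-sample
#'   vector `samples`
#' @export
phylogeneticHeritability <- function(result,
                                     denominator = c("all", "noGenus")) {
  denominator <- match.arg(denominator)
  stopifnot(is(result, "PhyloGLMMResult"))
  merged <- do.call(rbind, result@samples)
  den <- merged[, "vPhylo"] + merged[, "vResid"] +
    if (denominator == "all") merged[, "vGenus"] else 0
  h2 <- merged[, "vPhylo"] / den
  list(mean = mean(h2),
       lower95 = unname(stats::quantile(h2, 0.025)),
       upper95 = unname(stats::quantile(h2, 0.975)),
       samples = h2)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For m parallel chains of length L (per parameter), with W the mean
#' within-chain variance and B the between-chain variance of the chain
#' means times L, `PSRF = sqrt(((L-1)/L * W + B/L) / W)`. Values near 1
#' indicate the chains are sampling the same distribution.
#'
#' @param chains list of >= 2 aligned numeric matrices (or vectors) of
#'   equal length; matrices are diagnosed column-wise
#' @return named numeric vector of PSRFs per parameter
#' @examples
#' set.seed(1)
#' gelmanRubin(list(rnorm(500), rnorm(500)))
#' @export
gelmanRubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("Gelman-Rubin diagnostics need at least two chains")
  mats <- lapply(chains, function(x) if (is.matrix(x)) x else
    matrix(x, ncol = 1L, dimnames = list(NULL, "par")))
  L <- unique(vapply(mats, nrow, integer(1)))
  if (length(L) != 1L) stop("chains must have equal length")
  if (L < 10L) stop("chains too short for a meaningful diagnostic")
  pars <- colnames(mats[[1]])
  vapply(stats::setNames(pars, pars), function(p) {
    draws <- vapply(mats, function(m) m[, p], numeric(L))
    W <- mean(apply(draws, 2L, stats::var))
    B <- L * stats::var(colMeans(draws))
    sqrt(((L - 1) / L * W + B / L) / W)
  }, numeric(1))
}
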