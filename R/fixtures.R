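#' Packaged Enchenopa binotata study fixtures
#'
#' Returns the host-plant cladogram and the 61-record specimen/association
#' table for the *Enchenopa binotata* treehopper complex.
#'
#' The host tree spans the 15 host taxa in 8 angiosperm orders
#' (Celastrales, Dipsacales, Ericales, Fabales, Fagales, Magnoliales,
#' Malvales, Sapindales). The order-level backbone follows the published
#' angiosperm phylogenies the study design is based on (magnoliids sister
#' to rosids + asterids; within rosids the fabid orders Celastrales,
#' Fabales and Fagales versus the malvid pair Malvales + Sapindales;
#' within asterids Ericales sister to Dipsacales); within-order structure
#' places *Juglans nigra* and *J. cinerea* as sisters relative to *Carya*,
#' and in *Viburnum* makes *V. prunifolium* and *V. rufidulum* the closest
#' pair, joined successively by *V. lentago* and *V. cassinoides*. The
#' tree is stored as static data (it summarizes published phylogenies; it
#' is not computed by this package) and is a cladogram without branch
#' lengths.
#'
#' The association table transcribes the study's specimen collection
#' records: 61 *Enchenopa* individuals, of which 44 belong to the
#' *E. binotata* complex (15 host species, 10 host genera, Eastern North
#' America) and 17 are Central American outgroup specimens, mostly with
#' unknown host plants. Symbiont tips are labelled EN01..EN61 in table
#' order.
#'
#' @return a list with elements `host` (a `phylo` cladogram, tip labels
#'   with spaces, e.g. "Viburnum lentago") and `associations` (an
#'   `associationTable`, see [readAssociationTable()])
#' @examples
#' fx <- enchenopaFixture()
#' nrow(fx$associations)
#' @export
enchenopaFixture <- function() {
  nwk <- system.file("extdata", "enchenopa_host_tree.nwk",
                     package = "cophylotrack", mustWork = TRUE)
  tsv <- system.file("extdata", "enchenopa_associations.tsv",
                     package = "cophylotrack", mustWork = TRUE)
  host <- parseNewick(paste(readLines(nwk, warn = FALSE), collapse = ""),
                      underscores = "space")
  list(host = host, associations = readAssociationTable(tsv))
}
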