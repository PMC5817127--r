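#' Read a symbiont-host association table
#'
#' Reads a tab-separated table with a header row containing at least the
#' columns `symbiont_tip` and `host`. Multiple hosts for one symbiont tip
#' are separated by ";". Host names are whitespace-trimmed; a `genus`
#' column is derived as the first whitespace-delimited token of the host
#' name when not given explicitly. A host field that is empty or reads
#' "Unknown" (case-insensitive) marks the record as unmapped (host set
#' empty) rather than erroring: collection tables routinely mix ingroup
#' records with outgroup specimens lacking host data.
#'
#' @param file path to a TSV file, or a connection
#' @return a data.frame of class `associationTable` with columns
#'   `symbiont_tip`, `hosts` (list column of character vectors), `genus`
#'   (list column), `unmapped` (logical), `species` (if present), plus any
#'   further metadata columns from the file
#' @seealso [buildTanglegram()], [enchenopaFixture()]
#' @export
readAssociationTable <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  asAssociationTable(df)
}

#' Validate a data.frame as an association table
#'
#' @param df a data.frame with at least `symbiont_tip` and `host` columns
#'   (`host` may hold ";"-separated multi-host fields)
#' @return the validated `associationTable` (see [readAssociationTable()])
#' @export
asAssociationTable <- function(df) {
  need <- c("symbiont_tip", "host")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("association table schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  tip <- trimws(as.character(df$symbiont_tip))
  tip[is.na(df$symbiont_tip)] <- ""
  if (any(!nzchar(tip)))
    stop("association table: empty symbiont tip label in row(s) ",
         paste(which(!nzchar(tip)), collapse = ", "))
  if (anyDuplicated(tip))
    stop("association table uniqueness error: duplicate symbiont tip ",
         "label(s): ", paste(unique(tip[duplicated(tip)]), collapse = ", "))
  rawHost <- as.character(df$host)
  rawHost[is.na(rawHost)] <- ""
  hosts <- lapply(strsplit(rawHost, ";", fixed = TRUE), function(h) {
    h <- trimws(h)
    h[nzchar(h) & tolower(h) != "unknown"]
  })
  unmapped <- lengths(hosts) == 0L
  genus <- if ("genus" %in% names(df)) {
    g <- trimws(as.character(df$genus))
    lapply(seq_along(hosts), function(i)
      if (nzchar(g[i])) g[i] else firstToken(hosts[[i]]))
  } else {
    lapply(hosts, firstToken)
  }
  out <- df[setdiff(names(df), c("symbiont_tip", "host", "genus"))]
  out <- cbind(data.frame(symbiont_tip = tip, stringsAsFactors = FALSE), out)
  out$hosts <- hosts
  out$genus <- genus
  out$unmapped <- unmapped
  class(out) <- c("associationTable", "data.frame")
  out
}

firstToken <- function(x) unique(vapply(
  x, function(s) strsplit(s, "\\s+")[[1]][1], character(1),
  USE.NAMES = FALSE))

#' Construct a Tanglegram directly from trees and an association list
#'
#' Low-level constructor; see [buildTanglegram()] for building from an
#' association table with unmapped-record handling.
#'
#' @param host,symbiont rooted binary `phylo` trees
#' @param assoc named list mapping each symbiont tip label to a character
#'   vector of host tip labels
#' @return a [Tanglegram-class] object
#' @export
tanglegram <- function(host, symbiont, assoc) {
  new("Tanglegram", host = host, symbiont = symbiont,
      assoc = assoc[symbiont$tip.label])
}

#' Assemble a Tanglegram from trees and an association table
#'
#' Joins a host tree, a symbiont tree and an association table into the
#' validated input object of [reconcile()]. With `dropUnmapped = TRUE`,
#' records whose host set contains no tip of the host tree (including
#' records flagged unmapped) are excluded and the corresponding symbiont
#' tips pruned from the symbiont tree; the number of exclusions is
#' reported via `message()`. With `dropUnmapped = FALSE` any unmappable
#' record is an error listing the offending labels.
#'
#' @param host,symbiont rooted binary `phylo` trees
#' @param assoc an `associationTable` (see [readAssociationTable()]) or a
#'   named list of host-label vectors
#' @param dropUnmapped drop records not mappable onto the host tree?
#' @return a [Tanglegram-class] object
#' @examples
#' h <- parseNewick("((h1,h2),h3);")
#' s <- parseNewick("((p1,p2),p3);")
#' at <- asAssociationTable(data.frame(
#'   symbiont_tip = c("p1", "p2", "p3"),
#'   host = c("h1", "h2", "h3")))
#' buildTanglegram(h, s, at)
#' @export
buildTanglegram <- function(host, symbiont, assoc, dropUnmapped = FALSE) {
  if (!isBinaryTree(host)) stop("host tree is not rooted binary")
  if (!isBinaryTree(symbiont)) stop("symbiont tree is not rooted binary")
  if (inherits(assoc, "associationTable")) {
    alist <- assoc$hosts
    names(alist) <- assoc$symbiont_tip
  } else {
    alist <- assoc
  }
  stips <- symbiont$tip.label
  norec <- setdiff(stips, names(alist))
  if (length(norec))
    stop("symbiont tip(s) without an association record: ",
         paste(norec, collapse = ", "))
  alist <- alist[names(alist) %in% stips]
  mapped <- lapply(alist, function(h) intersect(h, host$tip.label))
  if (!dropUnmapped) {
    unknown <- setdiff(unlist(alist, use.names = FALSE), host$tip.label)
    empty <- names(mapped)[lengths(mapped) == 0L]
    if (length(unknown) || length(empty))
      stop("unmappable association record(s): ",
           if (length(empty))
             paste0("symbiont tip(s) ", paste(empty, collapse = ", "),
                    " have no host in the host tree; ") else "",
           if (length(unknown))
             paste0("host label(s) absent from host tree: ",
                    paste(unknown, collapse = ", ")) else "")
  }
  bad <- names(mapped)[lengths(mapped) == 0L]
  if (length(bad)) {
    message("buildTanglegram: dropped ", length(bad),
            " unmappable record(s)")
    keep <- setdiff(stips, bad)
    if (length(keep) < 1L)
      stop("no mappable symbiont tips remain")
    symbiont <- if (length(keep) == length(stips)) symbiont else
      ape::keep.tip(symbiont, keep)
    mapped <- mapped[symbiont$tip.label]
  }
  # partially mappable records: keep the mappable subset, note the rest
  lost <- sum(lengths(alist[names(mapped)]) - lengths(mapped))
  if (lost > 0L)
    message("buildTanglegram: ignored ", lost,
            " host label(s) absent from the host tree in otherwise ",
            "mappable records")
  tanglegram(host, symbiont, mapped)
}
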