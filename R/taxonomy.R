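#' Canonical taxonomic ranks, coarsest first
#'
#' The rank vocabulary used throughout the package. `"unclassified"` marks
#' the unclassified-reads pseudo-node of a Kraken report and `"other"` covers
#' non-canonical levels (root, clades, strain sub-levels such as `S1`).
#'
#' @format Character vector of rank names.
#' @export
CANONICAL_RANKS <- c("domain", "kingdom", "phylum", "class", "order",
                     "family", "genus", "species")

ALL_RANKS <- c(CANONICAL_RANKS, "unclassified", "other")

#' Construct a taxonomy table
#'
#' A taxonomy is a plain `data.frame` (class `"taxonomy"`) with one row per
#' taxon and columns `taxid`, `parent_taxid`, `rank`, `name`. Roots (and the
#' unclassified pseudo-node) have `parent_taxid = NA`.
#'
#' @param taxid Positive integer identifiers, unique. The Kraken convention
#'   of taxid 0 for unclassified reads is accepted.
#' @param parent_taxid Integer parent identifiers (`NA` for a root).
#' @param rank Character ranks; must be one of [CANONICAL_RANKS],
#'   `"unclassified"` or `"other"`.
#' @param name Character taxon names.
#' @return A `taxonomy` data.frame.
#' @examples
#' taxonomy(taxid = c(1, 2, 562), parent_taxid = c(NA, 1, 2),
#'          rank = c("other", "domain", "species"),
#'          name = c("root", "Bacteria", "Escherichia coli"))
#' @export
taxonomy <- function(taxid, parent_taxid, rank, name) {
  taxid <- as.integer(taxid)
  parent_taxid <- as.integer(parent_taxid)
  rank <- as.character(rank)
  name <- as.character(name)
  if (anyNA(taxid) || any(taxid < 0))
    stop("taxids must be non-negative integers")
  if (anyDuplicated(taxid))
    stop("duplicate taxid in taxonomy: ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  bad <- setdiff(rank, ALL_RANKS)
  if (length(bad))
    stop("unknown rank(s): ", paste(bad, collapse = ", "))
  orphan <- !is.na(parent_taxid) & !(parent_taxid %in% taxid)
  if (any(orphan))
    stop("parent_taxid not present in taxonomy for taxid(s): ",
         paste(taxid[orphan], collapse = ", "))
  out <- data.frame(taxid = taxid, parent_taxid = parent_taxid,
                    rank = rank, name = name, stringsAsFactors = FALSE)
  class(out) <- c("taxonomy", "data.frame")
  out
}

#' Read / write a taxonomy as 4-column TSV
#'
#' Plain-text serialization (`taxid`, `parent_taxid`, `rank`, `name`) so
#' simulated runs need no external taxonomy dump.
#'
#' @param path File path.
#' @return `read_taxonomy_tsv` returns a [taxonomy()]; `write_taxonomy_tsv`
#'   returns `path` invisibly.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          quote = "", stringsAsFactors = FALSE)
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% names(df)))
    stop("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
  taxonomy(df$taxid, df$parent_taxid, df$rank, df$name)
}

#' @param tax A [taxonomy()].
#' @rdname read_taxonomy_tsv
#' @export
write_taxonomy_tsv <- function(tax, path) {
  utils::write.table(as.data.frame(tax)[, c("taxid", "parent_taxid",
                                            "rank", "name")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# Named integer parent lookup (by taxid as character); NA for roots.
.parent_map <- function(tax) {
  p <- tax$parent_taxid
  names(p) <- as.character(tax$taxid)
  p
}

#' Lineage of a taxon
#'
#' Returns the chain of taxids from the taxon itself up to its root
#' (inclusive at both ends).
#'
#' @param tax A [taxonomy()].
#' @param taxid A single taxid present in `tax`.
#' @return Integer vector, taxon first, root last.
#' @export
tax_lineage <- function(tax, taxid) {
  pm <- .parent_map(tax)
  key <- as.character(taxid)
  if (!key %in% names(pm)) stop("taxid ", taxid, " not in taxonomy")
  out <- integer(0)
  while (!is.na(key)) {
    out <- c(out, as.integer(key))
    nxt <- pm[[key]]
    key <- if (is.na(nxt)) NA_character_ else as.character(nxt)
    if (length(out) > length(pm)) stop("cycle detected in taxonomy")
  }
  out
}

#' Ancestor of each taxon at a given rank
#'
#' Walks each taxon's lineage towards the root and returns the first node
#' declared at `rank` (the taxon itself qualifies). `NA` when the lineage
#' holds no node at that rank.
#'
#' @param tax A [taxonomy()].
#' @param taxids Integer vector of taxids in `tax`.
#' @param rank A canonical rank name.
#' @return Integer vector of ancestor taxids, `NA` where absent.
#' @export
tax_ancestor_at_rank <- function(tax, taxids, rank) {
  if (!rank %in% CANONICAL_RANKS)
    stop("not a canonical rank: ", rank)
  pm <- .parent_map(tax)
  rk <- tax$rank
  names(rk) <- as.character(tax$taxid)
  vapply(as.character(taxids), function(key) {
    if (!key %in% names(pm)) stop("taxid ", key, " not in taxonomy")
    while (!is.na(key)) {
      if (identical(rk[[key]], rank)) return(as.integer(key))
      nxt <- pm[[key]]
      key <- if (is.na(nxt)) NA_character_ else as.character(nxt)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Is each taxon a descendant of (or equal to) an ancestor taxon?
#'
#' @param tax A [taxonomy()].
#' @param taxids Integer vector of taxids to test.
#' @param ancestor Single taxid.
#' @return Logical vector.
#' @export
tax_is_descendant <- function(tax, taxids, ancestor) {
  pm <- .parent_map(tax)
  anc <- as.character(ancestor)
  vapply(as.character(taxids), function(key) {
    while (!is.na(key)) {
      if (identical(key, anc)) return(TRUE)
      nxt <- pm[[key]]
      key <- if (is.na(nxt)) NA_character_ else as.character(nxt)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}
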