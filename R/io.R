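# Kraken 2 report and Bracken species-output readers/writers.
#
# The Kraken 2 report is a headerless TSV: percent of reads in the clade,
# clade read count, reads assigned directly to the taxon, rank code, taxid,
# and the taxon name indented by two spaces per level of the taxonomy tree.
# Newer Kraken builds insert two minimizer columns before the rank code;
# both layouts are accepted.

KRAKEN_RANK_CODES <- c(U = "unclassified", R = "other", D = "domain",
                       K = "kingdom", P = "phylum", C = "class",
                       O = "order", F = "family", G = "genus", S = "species")

.rank_from_code <- function(code) {
  base <- KRAKEN_RANK_CODES[substr(code, 1, 1)]
  # sub-level codes (S1, G2, ...) and unknown codes map to "other"
  ifelse(is.na(base) | nchar(code) > 1, "other", base)
}

.code_from_rank <- function(rank) {
  codes <- stats::setNames(names(KRAKEN_RANK_CODES), KRAKEN_RANK_CODES)
  out <- codes[rank]
  out[is.na(out) | rank == "other"] <- "-"
  unname(out)
}

#' Read one sample from a Kraken 2 report
#'
#' Parses direct (taxon-level) read counts and reconstructs the taxon tree
#' from the two-space indentation of the name column, so no external
#' taxonomy dump is needed. Clade counts are parsed for validation only:
#' a line whose clade count is below its direct count is rejected, and a
#' parent clade smaller than the sum of its children raises a warning.
#'
#' @param path Path to a Kraken 2 report.
#' @param tax Optional existing [taxonomy()] to merge newly seen taxa into
#'   (taxa already known keep their registered rank/parent).
#' @return List with `counts` (named numeric, direct reads by taxid),
#'   `clade` (named numeric, clade reads by taxid) and `taxonomy` (the
#'   merged [taxonomy()]).
#' @export
read_kraken_report <- function(path, tax = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  taxid <- integer(n); parent <- integer(n); rank <- character(n)
  name <- character(n); direct <- numeric(n); clade <- numeric(n)
  stack_id <- integer(0); stack_depth <- integer(0)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 8L) f <- f[c(1, 2, 3, 6, 7, 8)]
    if (length(f) != 6L)
      stop("line ", i, ": expected 6 (or 8) tab-separated fields, got ",
           length(f))
    cl <- suppressWarnings(as.numeric(f[2]))
    di <- suppressWarnings(as.numeric(f[3]))
    ti <- suppressWarnings(as.integer(f[5]))
    if (is.na(cl) || is.na(di) || is.na(ti))
      stop("line ", i, ": non-numeric count or taxid")
    if (cl < di)
      stop("line ", i, ": clade reads (", cl,
           ") < direct reads (", di, ")")
    raw_name <- f[6]
    depth <- (nchar(raw_name) - nchar(sub("^ *", "", raw_name))) %/% 2L
    rk <- .rank_from_code(f[4])
    if (identical(rk, "unclassified")) {
      par <- NA_integer_
      stack_id <- integer(0); stack_depth <- integer(0)
    } else {
      keep <- stack_depth < depth
      stack_id <- stack_id[keep]; stack_depth <- stack_depth[keep]
      par <- if (length(stack_id)) stack_id[length(stack_id)] else NA_integer_
      stack_id <- c(stack_id, ti); stack_depth <- c(stack_depth, depth)
    }
    taxid[i] <- ti; parent[i] <- par; rank[i] <- rk
    name[i] <- sub("^ *", "", raw_name)
    direct[i] <- di; clade[i] <- cl
  }
  if (anyDuplicated(taxid))
    stop("duplicate taxid in report: ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  # clade consistency: parent clade >= sum of child clades
  if (n) {
    child_sum <- tapply(clade, factor(parent, levels = taxid), sum)
    bad <- which(!is.na(child_sum) & child_sum > clade + 1e-9)
    if (length(bad))
      warning("clade counts smaller than the sum of child clades for taxid(s): ",
              paste(taxid[bad], collapse = ", "))
  }
  new_tax <- if (n) taxonomy(taxid, parent, rank, name) else
    taxonomy(integer(0), integer(0), character(0), character(0))
  if (!is.null(tax)) {
    add <- !(new_tax$taxid %in% tax$taxid)
    merged <- rbind(as.data.frame(tax), as.data.frame(new_tax)[add, ])
    new_tax <- taxonomy(merged$taxid, merged$parent_taxid,
                        merged$rank, merged$name)
  }
  list(counts = stats::setNames(direct, as.character(taxid)),
       clade = stats::setNames(clade, as.character(taxid)),
       taxonomy = new_tax)
}

#' Write one sample as a Kraken 2 report
#'
#' Clade counts are recomputed as subtree sums of the supplied direct
#' counts; taxa whose subtree holds no reads are omitted, as Kraken does.
#' Siblings are printed by decreasing clade count (ties by taxid).
#'
#' @param counts Named numeric vector of direct read counts (names are
#'   taxids present in `tax`; taxid 0 is the unclassified pseudo-node).
#' @param tax A [taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kraken_report <- function(counts, tax, path) {
  direct <- stats::setNames(rep(0, nrow(tax)), as.character(tax$taxid))
  if (length(counts)) {
    if (!all(names(counts) %in% names(direct)))
      stop("counts contain taxids absent from the taxonomy")
    direct[names(counts)] <- as.numeric(counts)
  }
  pm <- .parent_map(tax)
  kids <- split(as.character(tax$taxid),
                factor(as.character(tax$parent_taxid),
                       levels = as.character(tax$taxid)))
  clade <- direct
  # accumulate leaves-to-root: process nodes in reverse topological order
  depth_of <- vapply(as.character(tax$taxid), function(k) {
    d <- 0L
    while (!is.na(pm[[k]])) { k <- as.character(pm[[k]]); d <- d + 1L }
    d
  }, integer(1))
  for (k in names(sort(depth_of, decreasing = TRUE))) {
    p <- pm[[k]]
    if (!is.na(p)) clade[[as.character(p)]] <-
        clade[[as.character(p)]] + clade[[k]]
  }
  total <- sum(direct)
  rk <- stats::setNames(tax$rank, as.character(tax$taxid))
  nm <- stats::setNames(tax$name, as.character(tax$taxid))
  out <- character(0)
  emit <- function(id, depth) {
    if (clade[[id]] <= 0) return()
    code <- if (identical(rk[[id]], "other") && identical(nm[[id]], "root"))
      "R" else .code_from_rank(rk[[id]])
    out[[length(out) + 1L]] <<- sprintf(
      "%6.2f\t%d\t%d\t%s\t%s\t%s%s",
      if (total > 0) 100 * clade[[id]] / total else 0,
      as.integer(clade[[id]]), as.integer(direct[[id]]), code, id,
      strrep(" ", 2L * depth), nm[[id]])
    ch <- kids[[id]]
    if (!is.null(ch) && length(ch)) {
      ch <- ch[order(-clade[ch], as.integer(ch))]
      for (c in ch) emit(c, depth + 1L)
    }
  }
  roots <- as.character(tax$taxid[is.na(tax$parent_taxid)])
  uncl <- roots[rk[roots] == "unclassified"]
  for (r in uncl) emit(r, 0L)
  for (r in setdiff(roots, uncl)) emit(r, 0L)
  writeLines(out, path)
  invisible(path)
}

BRACKEN_HEADER <- c("name", "taxonomy_id", "taxonomy_lvl",
                    "kraken_assigned_reads", "added_reads",
                    "new_est_reads", "fraction_total_reads")

#' Read one sample from a Bracken species output
#'
#' Returns the re-estimated species-level read counts (`new_est_reads`).
#' The `fraction_total_reads` column is cross-checked against the counts
#' (tolerance 1e-4 per row); fractions summing above 1 + 1e-4 raise a
#' warning but counts are kept.
#'
#' @param path Path to a Bracken output TSV.
#' @return List with `counts` (named numeric, `new_est_reads` by taxid) and
#'   `table` (the full parsed data.frame).
#' @export
read_bracken_output <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(BRACKEN_HEADER %in% names(df)))
    stop("missing Bracken header field(s): ",
         paste(setdiff(BRACKEN_HEADER, names(df)), collapse = ", "))
  if (any(df$new_est_reads < 0) || any(df$kraken_assigned_reads < 0))
    stop("negative read counts in Bracken output")
  if (nrow(df)) {
    frac <- df$new_est_reads / sum(df$new_est_reads)
    if (any(abs(frac - df$fraction_total_reads) > 1e-4))
      warning("fraction_total_reads not recomputable from counts (>1e-4 off)")
    if (sum(df$fraction_total_reads) > 1 + 1e-4)
      warning("fraction_total_reads sum exceeds 1 + 1e-4; counts kept")
  }
  list(counts = stats::setNames(as.numeric(df$new_est_reads),
                                as.character(df$taxonomy_id)),
       table = df)
}

#' Write species counts in Bracken output format
#'
#' @param counts Named numeric vector of species read counts by taxid.
#' @param tax A [taxonomy()] supplying names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bracken_output <- function(counts, tax, path) {
  ids <- names(counts)
  idx <- match(as.integer(ids), tax$taxid)
  if (anyNA(idx)) stop("counts contain taxids absent from the taxonomy")
  tot <- sum(counts)
  df <- data.frame(name = tax$name[idx], taxonomy_id = ids,
                   taxonomy_lvl = "S",
                   kraken_assigned_reads = as.integer(counts),
                   added_reads = 0L,
                   new_est_reads = as.integer(counts),
                   fraction_total_reads = sprintf(
                     "%.5f", if (tot > 0) counts / tot else 0),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
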