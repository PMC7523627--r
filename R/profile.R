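#' Construct a taxonomic profile table
#'
#' The central container: a non-negative integer count matrix with taxa as
#' rows (rownames are taxids as character; the single sentinel row
#' `"unranked"` may appear after rank aggregation) and samples as columns,
#' together with the taxonomy the taxids live in and per-sample metadata.
#'
#' @param counts Integer matrix, taxa x samples; rownames taxids, colnames
#'   sample labels.
#' @param tax A [taxonomy()] covering every row taxid.
#' @param samples A data.frame with columns `label`, `host_fraction_nominal`
#'   (proportion in \[0,1\] or `NA` when unknown) and `total_reads`. Built
#'   with [sample_meta()].
#' @return A `profile_table` object.
#' @export
profile_table <- function(counts, tax, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max in principle
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxid rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample labels")
  ids <- setdiff(rownames(counts), "unranked")
  if (!all(ids %in% as.character(tax$taxid)))
    stop("count rows not in taxonomy: ",
         paste(setdiff(ids, as.character(tax$taxid)), collapse = ", "))
  if (!identical(sort(samples$label), sort(colnames(counts))))
    stop("sample metadata labels must match count columns")
  samples <- samples[match(colnames(counts), samples$label), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, taxonomy = tax, samples = samples),
            class = "profile_table")
}

#' Per-sample metadata
#'
#' @param label Unique, non-empty sample labels (convention: `MS`, `SS10`,
#'   `SS90`, `SS99` for 0/10/90/99 % host DNA).
#' @param host_fraction_nominal Nominal host-DNA proportion in \[0,1\], or
#'   `NA` when unknown.
#' @param total_reads Total reads in the sample (defaults to `NA`, filled
#'   from column sums by [assemble_profile()]).
#' @return data.frame with one row per sample.
#' @export
sample_meta <- function(label, host_fraction_nominal = NA_real_,
                        total_reads = NA_real_) {
  label <- as.character(label)
  if (any(!nzchar(label))) stop("sample labels must be non-empty")
  if (anyDuplicated(label)) stop("duplicate sample labels")
  hf <- rep_len(as.numeric(host_fraction_nominal), length(label))
  if (any(!is.na(hf) & (hf < 0 | hf > 1)))
    stop("host_fraction_nominal must be in [0,1]")
  data.frame(label = label, host_fraction_nominal = hf,
             total_reads = rep_len(as.numeric(total_reads), length(label)),
             stringsAsFactors = FALSE)
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("profile_table: %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}

#' Assemble a profile table from per-sample count columns
#'
#' Columns (named count vectors keyed by taxid, as returned by
#' [read_kraken_report()] or [read_bracken_output()]) are merged over the
#' union of their taxa; a taxon absent from a sample gets count 0.
#'
#' @param columns Named list of numeric vectors (names are taxids); list
#'   names are ignored in favour of `samples$label`.
#' @param tax Shared [taxonomy()].
#' @param samples [sample_meta()] data.frame, one row per column.
#' @return A [profile_table()].
#' @export
assemble_profile <- function(columns, tax, samples) {
  if (length(columns) != nrow(samples))
    stop("need exactly one sample_meta row per column")
  if (anyDuplicated(samples$label)) stop("duplicate sample labels")
  all_ids <- unique(unlist(lapply(columns, names)))
  # stable order: taxonomy order first, then any sentinel rows
  all_ids <- c(intersect(as.character(tax$taxid), all_ids),
               setdiff(all_ids, as.character(tax$taxid)))
  m <- matrix(0, nrow = length(all_ids), ncol = length(columns),
              dimnames = list(all_ids, samples$label))
  for (j in seq_along(columns)) {
    col <- columns[[j]]
    if (length(col)) m[names(col), j] <- as.numeric(col)
  }
  if (any(is.na(samples$total_reads)))
    samples$total_reads[is.na(samples$total_reads)] <-
      colSums(m)[is.na(samples$total_reads)]
  profile_table(m, tax, samples)
}

#' Aggregate a profile at a taxonomic rank
#'
#' Counts are summed into each taxon's nearest ancestor at the requested
#' rank (a taxon already at that rank maps to itself; sub-rank nodes such as
#' strains roll up through it). Taxa with no ancestor at the rank are pooled
#' into a sentinel `"unranked"` row so that per-sample totals are conserved
#' exactly.
#'
#' @param profile A [profile_table()].
#' @param rank A canonical rank name (see [CANONICAL_RANKS]).
#' @return A [profile_table()] whose rows are taxa at `rank` plus, possibly,
#'   `"unranked"`.
#' @export
aggregate_at_rank <- function(profile, rank) {
  if (!rank %in% CANONICAL_RANKS) stop("unknown rank: ", rank)
  ids <- rownames(profile$counts)
  real <- setdiff(ids, "unranked")
  anc <- tax_ancestor_at_rank(profile$taxonomy, as.integer(real), rank)
  groups <- stats::setNames(rep("unranked", length(ids)), ids)
  groups[real] <- ifelse(is.na(anc), "unranked", as.character(anc))
  agg <- rowsum(profile$counts, group = groups[ids], reorder = FALSE)
  # deterministic row order: taxonomy order, sentinel last
  ord <- c(intersect(as.character(profile$taxonomy$taxid), rownames(agg)),
           intersect("unranked", rownames(agg)))
  profile_table(agg[ord, , drop = FALSE], profile$taxonomy, profile$samples)
}

#' Label every taxon as host, target or off-target
#'
#' Reproduces the read-categorization used when evaluating a spiked mock
#' community against a host dilution series:
#' \describe{
#'   \item{`target-species`}{exactly one of the declared target species.}
#'   \item{`target-lineage`}{any other node inside the lineage of the
#'     expected genera: ancestors of a target genus (family, phylum, the
#'     containing domain) or other descendants of a target genus
#'     (congeneric species, strains).}
#'   \item{`host`}{the host taxon, its descendants, and its ancestors up to
#'     (but excluding) nodes shared with the target lineage.}
#'   \item{`ambiguous`}{nodes ancestral to both host and targets (root,
#'     "cellular organisms") and the unclassified pseudo-node; these are
#'     neither host nor microbial and are excluded from microbial totals.}
#'   \item{`off-target`}{everything else: microbial taxa outside the
#'     expected lineages.}
#' }
#'
#' @param profile A [profile_table()].
#' @param targets Integer vector of target species taxids.
#' @param host_taxid Single taxid rooting the host subtree.
#' @return Named character vector (names = count rownames), one label per
#'   taxon row. Labels partition the taxa.
#' @export
label_taxa <- function(profile, targets, host_taxid) {
  tax <- profile$taxonomy
  if (!length(targets)) stop("targets must be non-empty")
  missing <- setdiff(targets, tax$taxid)
  if (length(missing))
    stop("target taxid(s) absent from taxonomy: ",
         paste(missing, collapse = ", "))
  if (!host_taxid %in% tax$taxid)
    stop("host taxid ", host_taxid, " absent from taxonomy")

  host_lineage <- tax_lineage(tax, host_taxid)
  target_genera <- unique(tax_ancestor_at_rank(tax, targets, "genus"))
  target_genera <- target_genera[!is.na(target_genera)]
  # nodes on the lineage of any target (species or its genus) up to root
  target_anc <- unique(unlist(c(lapply(targets, tax_lineage, tax = tax),
                                lapply(target_genera, tax_lineage, tax = tax))))

  ids <- rownames(profile$counts)
  real <- as.integer(setdiff(ids, "unranked"))
  rk <- tax$rank[match(real, tax$taxid)]

  lab <- vapply(seq_along(real), function(i) {
    t <- real[i]
    if (identical(rk[i], "unclassified")) return("ambiguous")
    in_host_anc <- t %in% host_lineage        # t is an ancestor of host (or host)
    in_target_anc <- t %in% target_anc        # t is on a target lineage
    if (in_host_anc && in_target_anc) return("ambiguous")
    if (t %in% targets) return("target-species")
    if (in_host_anc || tax_is_descendant(tax, t, host_taxid))
      return("host")
    if (in_target_anc) return("target-lineage")
    for (g in target_genera)
      if (tax_is_descendant(tax, t, g)) return("target-lineage")
    "off-target"
  }, character(1))
  names(lab) <- as.character(real)
  if ("unranked" %in% ids) lab <- c(lab, unranked = "ambiguous")
  lab[ids]
}

#' Microbial read totals per sample
#'
#' Sum of counts over all microbial taxa (labels `target-species`,
#' `target-lineage`, `off-target`); host and ambiguous internal nodes are
#' excluded. This total is also the DNA-concentration proxy used by the
#' frequency-based contaminant test.
#'
#' @param profile A [profile_table()].
#' @param labels Labels from [label_taxa()] for the same profile.
#' @return Named numeric vector, one total per sample.
#' @export
microbial_totals <- function(profile, labels) {
  stopifnot(identical(names(labels), rownames(profile$counts)))
  microbial <- labels %in% c("target-species", "target-lineage", "off-target")
  colSums(profile$counts[microbial, , drop = FALSE])
}

#' Export / import a profile as long-format TSV
#'
#' Columns: `sample`, `taxid`, `name`, `rank`, `count`. Zero counts are
#' omitted on write and restored as zeros on read.
#'
#' @param profile A [profile_table()].
#' @param path File path.
#' @return `write_profile_tsv` returns `path` invisibly;
#'   `read_profile_tsv` returns a [profile_table()].
#' @export
write_profile_tsv <- function(profile, path) {
  tax <- profile$taxonomy
  ids <- rownames(profile$counts)
  idx <- match(ids, as.character(tax$taxid))
  long <- do.call(rbind, lapply(colnames(profile$counts), function(s) {
    cnt <- profile$counts[, s]
    keep <- cnt > 0
    data.frame(sample = s, taxid = ids[keep],
               name = ifelse(is.na(idx[keep]), "unranked",
                             tax$name[idx[keep]]),
               rank = ifelse(is.na(idx[keep]), "other",
                             tax$rank[idx[keep]]),
               count = cnt[keep], stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param tax Taxonomy to attach (the long format does not carry parent
#'   links).
#' @param samples Optional [sample_meta()]; defaults to bare labels.
#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path, tax, samples = NULL) {
  long <- utils::read.delim(path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
  need <- c("sample", "taxid", "count")
  if (!all(need %in% names(long)))
    stop("profile TSV must have columns: ", paste(need, collapse = ", "))
  labs <- unique(long$sample)
  if (is.null(samples)) samples <- sample_meta(labs)
  cols <- lapply(labs, function(s) {
    sub <- long[long$sample == s, ]
    stats::setNames(sub$count, as.character(sub$taxid))
  })
  assemble_profile(cols, tax, samples)
}
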