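# Classification of off-target genera by their association with the mock
# community (synthetic-associated) or the host spike-in (host-associated),
# from the two extreme samples of the dilution series.

#' Classify a genus by its MS:SS99 read ratio
#'
#' A genus is synthetic-associated when its reads track the mock community
#' (`ms > threshold * ss99`), host-associated when they track the host
#' spike-in (`ss99 > threshold * ms`), and non-specific otherwise. The
#' inequalities are strict, so a count exactly at the threshold ratio is
#' non-specific; a zero on one side with a positive other side satisfies
#' the strict inequality. Counts are compared directly (the dilution
#' series is sequenced to equal depth); set `as_fractions = TRUE` to
#' compare within-sample microbial fractions instead.
#'
#' @param ms_count,ss99_count Reads in the pure-community and the 99 %
#'   host sample; vectors recycle.
#' @param ratio_threshold Ratio defining association (default 10).
#' @param ms_total,ss99_total Microbial totals, required when
#'   `as_fractions = TRUE`.
#' @param as_fractions Compare `count / total` instead of raw counts.
#' @return Character vector in `synthetic-associated`, `host-associated`,
#'   `non-specific`.
#' @export
classify_association <- function(ms_count, ss99_count, ratio_threshold = 10,
                                 as_fractions = FALSE,
                                 ms_total = NULL, ss99_total = NULL) {
  if (any(ms_count < 0) || any(ss99_count < 0))
    stop("counts must be non-negative")
  if (any(ms_count == 0 & ss99_count == 0))
    stop("both counts zero: genus should have been filtered")
  a <- as.numeric(ms_count); b <- as.numeric(ss99_count)
  if (as_fractions) {
    if (is.null(ms_total) || is.null(ss99_total))
      stop("fraction mode needs ms_total and ss99_total")
    a <- a / ms_total; b <- b / ss99_total
  }
  ifelse(a > ratio_threshold * b, "synthetic-associated",
         ifelse(b > ratio_threshold * a, "host-associated", "non-specific"))
}

#' Association calls for all eligible off-target genera
#'
#' @param genus_profile A [profile_table()] aggregated at genus rank.
#' @param genus_labels Labels from [label_taxa()] on `genus_profile`.
#' @param ms,ss99 Labels of the pure-community and 99 %-host samples.
#' @param ratio_threshold See [classify_association()].
#' @param include Which label classes to call (default off-target genera
#'   only). Genera with zero reads in both extreme samples are classed
#'   `non-specific` (the rule only references MS and SS99).
#' @return data.frame: `taxid`, `name`, `ms_count`, `ss99_count`, `class`.
#' @export
association_calls <- function(genus_profile, genus_labels,
                              ms = "MS", ss99 = "SS99",
                              ratio_threshold = 10,
                              include = "off-target") {
  stopifnot(all(c(ms, ss99) %in% colnames(genus_profile$counts)))
  ids <- rownames(genus_profile$counts)
  keep <- genus_labels[ids] %in% include &
    rowSums(genus_profile$counts[, c(ms, ss99), drop = FALSE]) >= 0
  ids <- ids[keep]
  a <- genus_profile$counts[ids, ms]
  b <- genus_profile$counts[ids, ss99]
  cls <- rep("non-specific", length(ids))
  eligible <- (a + b) > 0
  cls[eligible] <- classify_association(a[eligible], b[eligible],
                                        ratio_threshold)
  tx <- genus_profile$taxonomy
  nm <- tx$name[match(ids, as.character(tx$taxid))]
  nm[is.na(nm)] <- ids[is.na(nm)]
  data.frame(taxid = ids, name = nm, ms_count = a, ss99_count = b,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Off-target burden summary
#'
#' Per-sample fractions of microbial reads that are off-target, and the
#' split of microbial reads across association classes; plus the census of
#' off-target genera whose reads in a reference sample meet or exceed the
#' smallest target-genus count there (the "contaminants outnumber real
#' community members" comparison).
#'
#' @param genus_profile A [profile_table()] at genus rank.
#' @param genus_labels Labels from [label_taxa()] on `genus_profile`.
#' @param calls data.frame from [association_calls()].
#' @param reference_sample Sample used for the census (default `"SS99"`).
#' @param target_genera Taxids of the target genera (used for the census
#'   floor); defaults to genera labelled `target-lineage` that directly
#'   contain a target, i.e. all genus rows labelled `target-lineage`.
#' @return List: `offtarget_fraction` (per sample), `class_fractions`
#'   (matrix class x sample, fractions of microbial reads),
#'   `reference_floor` (smallest target-genus count in the reference
#'   sample), `n_offtarget_at_floor` (off-target genera with at least that
#'   many reads there), `top_offtarget` (census rows, decreasing counts).
#' @export
offtarget_summary <- function(genus_profile, genus_labels, calls,
                              reference_sample = "SS99",
                              target_genera = NULL) {
  cnt <- genus_profile$counts
  micro <- microbial_totals(genus_profile, genus_labels)
  off_ids <- names(genus_labels)[genus_labels == "off-target"]
  off_ids <- intersect(off_ids, rownames(cnt))
  offtarget_fraction <- colSums(cnt[off_ids, , drop = FALSE]) / micro
  classes <- c("synthetic-associated", "host-associated", "non-specific")
  class_fractions <- sapply(colnames(cnt), function(s) {
    vapply(classes, function(cl) {
      ids <- calls$taxid[calls$class == cl]
      sum(cnt[intersect(ids, rownames(cnt)), s]) / micro[[s]]
    }, numeric(1))
  })
  if (is.null(target_genera)) {
    target_genera <- names(genus_labels)[genus_labels == "target-lineage"]
    target_genera <- intersect(target_genera, rownames(cnt))
    rk <- genus_profile$taxonomy$rank[
      match(target_genera, as.character(genus_profile$taxonomy$taxid))]
    target_genera <- target_genera[!is.na(rk) & rk == "genus"]
  } else target_genera <- as.character(target_genera)
  floor_count <- if (length(target_genera))
    min(cnt[target_genera, reference_sample]) else NA_real_
  census <- cnt[off_ids, reference_sample]
  at_floor <- if (is.na(floor_count)) character(0)
    else off_ids[census >= floor_count]
  tx <- genus_profile$taxonomy
  top <- data.frame(taxid = at_floor,
                    name = tx$name[match(at_floor, as.character(tx$taxid))],
                    count = cnt[at_floor, reference_sample],
                    row.names = NULL, stringsAsFactors = FALSE)
  top <- top[order(-top$count, top$taxid), , drop = FALSE]
  list(offtarget_fraction = offtarget_fraction,
       class_fractions = class_fractions,
       reference_floor = floor_count,
       n_offtarget_at_floor = length(at_floor),
       top_offtarget = top)
}
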