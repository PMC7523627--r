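# Frequency-based contaminant identification for taxonomic profiles.
#
# A constant-mass contaminant's frequency among microbial reads varies
# inversely with the total microbial DNA in the sample. With no DNA
# quantitation available, total microbial read count stands in as the
# concentration proxy. For each species, two nested models are fit to
# log10 frequency vs log10 concentration over the samples where the
# species is present:
#   contaminant model:      log10 f = -log10 C + b0   (slope fixed at -1)
#   non-contaminant model:  log10 f = b1              (constant)
# both intercepts by least squares. The score maps the residual
# sum-of-squares ratio through the survival function of an F distribution
# with (n-1, n-1) degrees of freedom, evaluated at SSE_non / SSE_cont:
# scores near 0 mean the inverse-frequency (contaminant) model fits much
# better.

#' Frequency-model contaminant score for one species
#'
#' @param freq Species frequencies (species reads / microbial reads) over
#'   samples where the species has positive reads. Frequencies of exactly
#'   1 (single-species samples) are degenerate and excluded.
#' @param conc Matching concentration proxies (total microbial reads),
#'   positive.
#' @param min_samples Minimum number of usable samples (default 3).
#' @return List: `score` in \[0,1\] (`NA` with `status =
#'   "insufficient-data"` when too few samples or zero-variance
#'   concentrations), `n_samples_used`, `status` (`"ok"` or
#'   `"insufficient-data"`).
#' @export
frequency_score <- function(freq, conc, min_samples = 3) {
  keep <- !is.na(freq) & freq > 0 & freq < 1 & conc > 0
  f <- freq[keep]; C <- conc[keep]
  n <- length(f)
  if (n < min_samples || stats::sd(log10(C)) == 0)
    return(list(score = NA_real_, n_samples_used = n,
                status = "insufficient-data"))
  lf <- log10(f); lC <- log10(C)
  # contaminant: residuals of (lf + lC) around its mean; slope -1 fixed
  r_cont <- (lf + lC) - mean(lf + lC)
  sse_cont <- sum(r_cont^2)
  r_non <- lf - mean(lf)
  sse_non <- sum(r_non^2)
  score <- if (sse_cont == 0 && sse_non == 0) 1
  else if (sse_cont == 0) 0
  else if (sse_non == 0) 1
  else stats::pf(sse_non / sse_cont, n - 1, n - 1, lower.tail = FALSE)
  list(score = score, n_samples_used = n, status = "ok")
}

#' Contaminant calls for every microbial species in a profile
#'
#' Applies [frequency_score()] to each species-rank microbial taxon with
#' any positive count, using total microbial reads as the concentration
#' proxy. A species is called `contaminant` when its score is below
#' `threshold` and enough samples were usable; species present in fewer
#' than `min_samples` samples are `insufficient-data`.
#'
#' @param profile A species-level [profile_table()].
#' @param labels Labels from [label_taxa()] for the same profile.
#' @param threshold Score threshold for the contaminant call
#'   (default 0.1).
#' @param min_samples Minimum positive samples per species (default 3).
#' @return data.frame (`contaminant_calls`): `taxid`, `name`, `label`,
#'   `score`, `call`, `n_samples_used`.
#' @export
call_contaminants <- function(profile, labels, threshold = 0.1,
                              min_samples = 3) {
  if (ncol(profile$counts) < 2)
    stop("frequency-based identification needs >= 2 samples")
  stopifnot(identical(names(labels), rownames(profile$counts)))
  micro <- microbial_totals(profile, labels)
  tx <- profile$taxonomy
  ids <- rownames(profile$counts)
  rk <- tx$rank[match(ids, as.character(tx$taxid))]
  eligible <- labels %in% c("target-species", "target-lineage", "off-target") &
    !is.na(rk) & rk == "species" & rowSums(profile$counts) > 0
  ids <- ids[eligible]
  res <- lapply(ids, function(id) {
    cnt <- profile$counts[id, ]
    frequency_score(cnt / micro, micro, min_samples = min_samples)
  })
  score <- vapply(res, `[[`, numeric(1), "score")
  nuse <- vapply(res, `[[`, numeric(1), "n_samples_used")
  status <- vapply(res, `[[`, character(1), "status")
  call <- ifelse(status != "ok", "insufficient-data",
                 ifelse(score < threshold, "contaminant", "not-contaminant"))
  out <- data.frame(taxid = ids,
                    name = tx$name[match(ids, as.character(tx$taxid))],
                    label = unname(labels[ids]), score = score, call = call,
                    n_samples_used = as.integer(nuse),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "min_samples") <- min_samples
  out
}

#' Remove called contaminants from a profile
#'
#' Zeroes the counts of every species called `contaminant` and reports
#' removal statistics: per-sample fractions of off-target reads and of
#' off-target species removed, and the retained counts of the target
#' species.
#'
#' @param profile The [profile_table()] the calls were computed on.
#' @param calls data.frame from [call_contaminants()].
#' @param labels Labels from [label_taxa()] for the same profile.
#' @return List: `filtered` (profile with contaminant rows zeroed),
#'   `stats` with `offtarget_reads_removed` and
#'   `offtarget_species_removed` (named per sample), `n_called`,
#'   `target_retained` (count matrix of target species after filtering).
#' @export
filter_contaminants <- function(profile, calls, labels) {
  stopifnot(identical(names(labels), rownames(profile$counts)))
  called <- calls$taxid[calls$call == "contaminant"]
  cnt <- profile$counts
  filtered <- cnt
  filtered[intersect(called, rownames(cnt)), ] <- 0
  off_ids <- names(labels)[labels == "off-target"]
  off_ids <- intersect(off_ids, rownames(cnt))
  off_before <- colSums(cnt[off_ids, , drop = FALSE])
  off_after <- colSums(filtered[off_ids, , drop = FALSE])
  reads_removed <- ifelse(off_before > 0,
                          (off_before - off_after) / off_before, 0)
  sp_present <- cnt[off_ids, , drop = FALSE] > 0
  sp_removed_mat <- sp_present & off_ids %in% called
  species_removed <- ifelse(colSums(sp_present) > 0,
                            colSums(sp_removed_mat) / colSums(sp_present), 0)
  target_ids <- names(labels)[labels == "target-species"]
  fp <- profile_table(filtered, profile$taxonomy, profile$samples)
  list(filtered = fp,
       stats = list(offtarget_reads_removed = reads_removed,
                    offtarget_species_removed = species_removed,
                    n_called = length(called)),
       target_retained = filtered[intersect(target_ids, rownames(filtered)),
                                  , drop = FALSE])
}
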