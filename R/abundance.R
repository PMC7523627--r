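# Genome-size-normalized abundance estimation and accuracy metrics.
#
# Read counts are proportional to DNA mass, i.e. genome copies x genome
# size; dividing counts by genome size recovers relative genome-copy
# abundance, the scale on which a mock community's theoretical composition
# is declared.

#' Genome-size-normalized relative abundance
#'
#' `abundance_i = (count_i / size_i) / sum_j (count_j / size_j)`, computed
#' over the supplied target species only (off-target reads are discounted
#' by construction).
#'
#' @param counts Named numeric vector of per-target read counts.
#' @param genome_sizes Named numeric vector of genome sizes (bp), matching
#'   `names(counts)`.
#' @param basis Provenance of the counts, recorded not computed:
#'   `"raw"` (direct assignments) or `"re-estimated"` (Bracken-style).
#' @return Named numeric vector of proportions summing to 1, with
#'   attribute `basis`.
#' @export
genome_normalized_abundance <- function(counts, genome_sizes,
                                        basis = c("raw", "re-estimated")) {
  basis <- match.arg(basis)
  if (!all(names(counts) %in% names(genome_sizes)))
    stop("missing genome size for: ",
         paste(setdiff(names(counts), names(genome_sizes)), collapse = ", "))
  sizes <- genome_sizes[names(counts)]
  if (any(sizes <= 0)) stop("genome sizes must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all counts zero: composition undefined")
  dens <- counts / sizes
  structure(dens / sum(dens), basis = basis)
}

#' Observed/expected abundance ratios
#'
#' @param estimate Observed proportions (e.g. from
#'   [genome_normalized_abundance()]).
#' @param expected Theoretical proportions, all positive, summing to 1
#'   (within 1e-6); names must cover those of `estimate`.
#' @return Named numeric vector `observed / expected`. A zero observed
#'   count gives ratio 0 (detected-but-underestimated, not excluded).
#' @export
obs_exp_ratios <- function(estimate, expected) {
  miss <- setdiff(names(estimate), names(expected))
  if (length(miss))
    stop("no expected abundance for: ", paste(miss, collapse = ", "))
  expected <- expected[names(estimate)]
  if (any(expected <= 0)) stop("expected proportions must be positive")
  if (abs(sum(expected) - 1) > 1e-6)
    stop("expected proportions must sum to 1")
  stats::setNames(as.numeric(estimate) / as.numeric(expected),
                  names(estimate))
}

#' Mean squared relative error of an abundance estimate
#'
#' Mean over species of `((observed - expected) / expected)^2`.
#'
#' @param observed,expected Matched proportion vectors; `expected` all
#'   positive.
#' @return Non-negative scalar; 0 iff the estimate is exact.
#' @export
mean_squared_relative_error <- function(observed, expected) {
  if (!length(observed)) stop("empty species set")
  if (length(observed) != length(expected))
    stop("observed and expected must match")
  if (!is.null(names(observed)) && !is.null(names(expected))) {
    if (!setequal(names(observed), names(expected)))
      stop("observed and expected species sets differ")
    expected <- expected[names(observed)]
  }
  if (any(expected <= 0)) stop("expected proportions must be positive")
  mean(((observed - expected) / expected)^2)
}

#' Detection table
#'
#' A species is detected in a sample when its read count reaches
#' `min_reads` (default 1 read at species level).
#'
#' @param profile A [profile_table()].
#' @param targets Integer vector of target species taxids.
#' @param min_reads Detection threshold (>= 1).
#' @return List with `detected` (logical matrix, targets x samples) and
#'   `n_detected` (named integer per sample).
#' @export
detection_table <- function(profile, targets, min_reads = 1) {
  if (min_reads < 1) stop("min_reads must be >= 1")
  ids <- as.character(targets)
  m <- matrix(0, nrow = length(ids), ncol = ncol(profile$counts),
              dimnames = list(ids, colnames(profile$counts)))
  present <- intersect(ids, rownames(profile$counts))
  m[present, ] <- profile$counts[present, , drop = FALSE]
  det <- m >= min_reads
  list(detected = det, n_detected = colSums(det))
}

#' Count ratios inside a closed band
#'
#' @param ratios Numeric vector.
#' @param band Length-2 numeric `(low, high)`, `low < high`. Both
#'   boundaries are included. The "within 10 %" comparison of two
#'   estimates uses `band = c(0.9, 1.1)` on their ratio.
#' @return Integer count of ratios with `low <= r <= high`.
#' @export
count_within_band <- function(ratios, band = c(0.5, 2)) {
  if (length(band) != 2 || band[1] >= band[2])
    stop("band must be (low, high) with low < high")
  sum(ratios >= band[1] & ratios <= band[2], na.rm = TRUE)
}

#' Correlation of observed/expected ratio with genome GC content
#'
#' Pearson correlation between per-species observed/expected abundance
#' ratios and GC fractions; optionally on log10 ratios.
#'
#' @param ratios Named numeric vector of observed/expected ratios.
#' @param gc Named numeric vector of GC fractions, covering
#'   `names(ratios)`.
#' @param log Correlate `log10(ratios)` instead (drops non-positive
#'   ratios). Default `FALSE`.
#' @return Pearson r, or `NA` when either variable has zero variance.
#' @export
gc_ratio_correlation <- function(ratios, gc, log = FALSE) {
  if (length(ratios) < 3) stop("need >= 3 species")
  if (!is.null(names(ratios))) gc <- gc[names(ratios)]
  if (length(gc) != length(ratios) || anyNA(gc))
    stop("gc must cover all species in ratios")
  x <- as.numeric(ratios)
  if (log) {
    keep <- x > 0
    x <- log10(x[keep]); gc <- gc[keep]
    if (length(x) < 3) stop("need >= 3 species with positive ratios")
  }
  if (stats::sd(x) == 0 || stats::sd(gc) == 0) return(NA_real_)
  stats::cor(x, as.numeric(gc))
}

#' Per-sample accuracy report for target species
#'
#' Convenience wrapper chaining [genome_normalized_abundance()],
#' [obs_exp_ratios()], [mean_squared_relative_error()],
#' [count_within_band()] and [gc_ratio_correlation()] for one sample.
#'
#' @param counts Named per-target read counts for one sample.
#' @param design A `community_design` supplying genome sizes, GC and
#'   theoretical copies.
#' @param band Ratio band, default `c(0.5, 2)`.
#' @param basis Count provenance, see [genome_normalized_abundance()].
#' @return List: `abundance`, `expected`, `ratios`, `mse`,
#'   `n_within_band`, `band`, `gc_correlation`.
#' @export
accuracy_report <- function(counts, design, band = c(0.5, 2),
                            basis = "raw") {
  m <- design$members
  sizes <- stats::setNames(m$genome_size, as.character(m$taxid))
  gc <- stats::setNames(m$gc, as.character(m$taxid))
  expected <- stats::setNames(m$copies / sum(m$copies),
                              as.character(m$taxid))
  counts <- counts[as.character(m$taxid)]
  counts[is.na(counts)] <- 0
  names(counts) <- as.character(m$taxid)
  ab <- genome_normalized_abundance(counts, sizes, basis = basis)
  ratios <- obs_exp_ratios(ab, expected)
  list(abundance = ab, expected = expected, ratios = ratios,
       mse = mean_squared_relative_error(as.numeric(ab),
                                         as.numeric(expected)),
       n_within_band = count_within_band(ratios, band), band = band,
       gc_correlation = if (length(ratios) >= 3)
         gc_ratio_correlation(ratios, gc) else NA_real_)
}
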