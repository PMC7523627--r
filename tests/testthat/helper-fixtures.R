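# Small hand-built taxonomy: bacteria (two phyla, three genera) and a
# murine host lineage, with one congeneric non-target species.
tiny_taxonomy <- function() {
  taxonomy(
    taxid = c(1, 131567, 2, 2759,
              1224, 561, 562, 564, 620, 623,
              1239, 1279, 1280,
              7711, 10088, 10090),
    parent_taxid = c(NA, 1, 131567, 131567,
                     2, 1224, 561, 561, 1224, 620,
                     2, 1239, 1279,
                     2759, 7711, 10088),
    rank = c("other", "other", "domain", "domain",
             "phylum", "genus", "species", "species", "genus", "species",
             "phylum", "genus", "species",
             "phylum", "genus", "species"),
    name = c("root", "cellular organisms", "Bacteria", "Eukaryota",
             "Proteobacteria", "Escherichia", "Escherichia coli",
             "Escherichia fergusonii", "Shigella", "Shigella flexneri",
             "Firmicutes", "Staphylococcus", "Staphylococcus aureus",
             "Chordata", "Mus", "Mus musculus"))
}

tiny_targets <- c(562, 1280)
tiny_host <- 10090

# random taxonomy for conservation properties: node i attaches to a random
# earlier node, ranks drawn freely (aggregation must conserve totals for
# any tree shape)
random_taxonomy <- function(n) {
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  ranks <- c("other", sample(c(CANONICAL_RANKS, "other"), n - 1L,
                             replace = TRUE))
  taxonomy(seq_len(n), parent, ranks, paste0("node", seq_len(n)))
}

random_profile <- function(tax, n_samples = 3) {
  n <- nrow(tax)
  counts <- matrix(rpois(n * n_samples, lambda = 5), nrow = n,
                   dimnames = list(as.character(tax$taxid),
                                   paste0("S", seq_len(n_samples))))
  profile_table(counts, tax, sample_meta(paste0("S", seq_len(n_samples))))
}

# Independent brute-force route for the frequency score: intercepts by
# numeric minimization, F tail by numeric integration of the density.
oracle_frequency_score <- function(f, C) {
  lf <- log10(f); lC <- log10(C); n <- length(f)
  sse_cont <- stats::optimize(function(b) sum((lf - (-lC + b))^2),
                              interval = c(-100, 100), tol = 1e-12)$objective
  sse_non <- stats::optimize(function(b) sum((lf - b)^2),
                             interval = c(-100, 100), tol = 1e-12)$objective
  fstat <- sse_non / sse_cont
  stats::integrate(stats::df, lower = fstat, upper = Inf,
                   df1 = n - 1, df2 = n - 1,
                   rel.tol = 1e-12, abs.tol = 1e-13)$value
}
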