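test_that("genome-size normalization recovers genome-copy composition", {
  sizes <- c(a = 1e6, b = 2e6)
  ab <- genome_normalized_abundance(c(a = 100, b = 100), sizes)
  expect_equal(unname(ab[c("a", "b")]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # equal sizes: proportional to counts
  ab2 <- genome_normalized_abundance(c(a = 30, b = 10),
                                     c(a = 5e6, b = 5e6))
  expect_equal(unname(ab2[c("a", "b")]), c(0.75, 0.25), tolerance = 1e-12)
  # three-species hand case
  ab3 <- genome_normalized_abundance(c(a = 300, b = 100, c = 100),
                                     c(a = 3e6, b = 1e6, c = 1e6))
  expect_equal(as.numeric(ab3), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(genome_normalized_abundance(c(a = 0, b = 0), sizes),
               "all counts zero")
})

test_that("normalized abundance is scale-invariant, sums to 1 and permutes", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    counts <- stats::setNames(rpois(n, 50) + 1, paste0("s", 1:n))
    sizes <- stats::setNames(runif(n, 2e6, 7e6), names(counts))
    ab <- genome_normalized_abundance(counts, sizes)
    expect_equal(sum(ab), 1, tolerance = 1e-9)
    k <- runif(1, 0.1, 1000)
    expect_equal(as.numeric(genome_normalized_abundance(counts * k, sizes)),
                 as.numeric(ab), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(as.numeric(genome_normalized_abundance(counts[perm],
                                                        sizes)),
                 as.numeric(ab)[perm], tolerance = 1e-12)
  }
})

test_that("observed/expected ratios handle identity, doubling and zeros", {
  expect_equal(unname(obs_exp_ratios(c(a = 0.3, b = 0.7),
                                     c(a = 0.3, b = 0.7))),
               c(1, 1), tolerance = 1e-12)
  # doubled then renormalized pair: observed 2/3 vs expected 1/2
  expect_equal(unname(obs_exp_ratios(c(a = 2 / 3, b = 1 / 3),
                                     c(a = 0.5, b = 0.5))["a"]),
               4 / 3, tolerance = 1e-12)
  expect_equal(unname(obs_exp_ratios(c(a = 0, b = 1),
                                     c(a = 0.5, b = 0.5))["a"]), 0)
  expect_error(obs_exp_ratios(c(a = 1, z = 0), c(a = 0.5, b = 0.5)), "z")
})

test_that("mean squared relative error matches hand arithmetic", {
  expect_equal(mean_squared_relative_error(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(mean_squared_relative_error(c(0.6, 0.4), c(0.5, 0.5)),
               0.04, tolerance = 1e-12)
  # observed = 2x expected for every species (unnormalized input)
  expect_equal(mean_squared_relative_error(c(0.2, 0.6), c(0.1, 0.3)), 1,
               tolerance = 1e-12)
  expect_error(mean_squared_relative_error(numeric(0), numeric(0)),
               "empty")
})

test_that("mse is non-negative and zero only at exactness", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    e <- runif(n, 0.01, 1); e <- e / sum(e)
    o <- e * exp(rnorm(n, sd = 0.2)); o <- o / sum(o)
    m <- mean_squared_relative_error(o, e)
    expect_gte(m, 0)
    if (m == 0) expect_equal(o, e)
    expect_equal(mean_squared_relative_error(e, e), 0)
  }
})

test_that("detection respects the read threshold boundary", {
  tax <- tiny_taxonomy()
  prof <- assemble_profile(list(c(`562` = 5, `1280` = 1),
                                c(`562` = 4)),
                           tax, sample_meta(c("A", "B")))
  det <- detection_table(prof, tiny_targets, min_reads = 1)
  expect_equal(unname(det$n_detected), c(2, 1))
  # exactly-at-threshold counts are detected
  det5 <- detection_table(prof, tiny_targets, min_reads = 5)
  expect_true(det5$detected["562", "A"])
  expect_false(det5$detected["562", "B"])
  det99 <- detection_table(prof, tiny_targets, min_reads = 99)
  expect_equal(unname(det99$n_detected), c(0, 0))
  expect_error(detection_table(prof, tiny_targets, min_reads = 0),
               ">= 1")
})

test_that("ratio bands are closed intervals", {
  expect_equal(count_within_band(c(0.5, 2.0), c(0.5, 2)), 2)
  expect_equal(count_within_band(c(1, 1, 1), c(0.5, 2)), 3)
  expect_equal(count_within_band(c(0.49, 1.0, 2.01), c(0.5, 2)), 1)
  expect_equal(count_within_band(c(0.9, 1.1, 1.11), c(0.9, 1.1)), 2)
  expect_error(count_within_band(1, c(2, 0.5)), "low < high")
})

test_that("GC correlation matches the covariance formula and its limits", {
  gc <- c(a = 0.3, b = 0.4, c = 0.5, d = 0.6, e = 0.7)
  # perfectly decreasing linear relationship
  ratios <- stats::setNames(2 - 2 * gc, names(gc))
  expect_equal(gc_ratio_correlation(ratios, gc), -1, tolerance = 1e-12)
  # constant ratios: undefined
  expect_true(is.na(gc_ratio_correlation(stats::setNames(rep(1, 5),
                                                         names(gc)), gc)))
  # 5-point hand-computed case via the textbook formula
  r <- c(a = 1.2, b = 0.8, c = 1.5, d = 0.6, e = 1.0)
  num <- sum((r - mean(r)) * (gc - mean(gc)))
  den <- sqrt(sum((r - mean(r))^2) * sum((gc - mean(gc))^2))
  expect_equal(gc_ratio_correlation(r, gc), num / den, tolerance = 1e-12)
  expect_error(gc_ratio_correlation(c(a = 1, b = 2), c(a = .5, b = .6)),
               ">= 3")
})
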