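test_that("default design matches the declared community structure", {
  d <- build_default_design()
  m <- d$members
  expect_equal(nrow(m), 20)
  expect_equal(length(unique(m$genus_taxid)), 17)
  expect_gte(max(m$copies) / min(m$copies), 2000)
  expect_true(all(m$gc >= 0 & m$gc <= 1))
  expect_true(all(m$genome_size >= 2e6 & m$genome_size <= 7e6))
  expect_true(562 %in% m$taxid)   # the member wired to the confusion model
  expect_true("562" %in% names(default_confusion_model()))
})

test_that("default panel has the two contaminant modes", {
  p <- default_contaminant_panel()
  expect_equal(sum(p$mode == "host-associated"), 30)
  expect_equal(sum(p$mode == "reagent-constant"), 5)
  expect_true(all(p$mass_per_unit > 0))
  expect_equal(sum(p$mass_per_unit[p$mode == "host-associated"]), 0.002)
})

test_that("expected read fractions follow the DNA-mass model", {
  # two equal-copy species, sizes 4 Mb and 2 Mb, no host
  d <- structure(list(
    members = data.frame(name = c("a", "b"), taxid = c(11L, 12L),
                         copies = c(1, 1), genome_size = c(4e6, 2e6),
                         gc = c(0.5, 0.5)),
    host = list(name = "h", taxid = 99L, genome_size = 1e9, gc = 0.4)),
    class = "community_design")
  empty_panel <- default_contaminant_panel()[0, ]
  p0 <- expected_read_fractions(d, empty_panel, 0)
  expect_equal(unname(p0[c("11", "12")]), c(2 / 3, 1 / 3) * 1,
               tolerance = 1e-12)
  expect_equal(sum(p0), 1)
  # host fraction 0.99 with no contaminants
  p99 <- expected_read_fractions(d, empty_panel, 0.99)
  expect_equal(unname(p99["99"]), 0.99, tolerance = 1e-12)
  expect_true(all(p99 >= 0))
})

test_that("host-associated contaminant share scales with host fraction", {
  d <- structure(list(
    members = data.frame(name = "a", taxid = 11L, copies = c(1, 1)[1],
                         genome_size = 4e6, gc = 0.5),
    host = list(name = "h", taxid = 99L, genome_size = 1e9, gc = 0.4)),
    class = "community_design")
  d$members <- rbind(d$members,
                     data.frame(name = "b", taxid = 12L, copies = 1,
                                genome_size = 2e6, gc = 0.5))
  panel <- data.frame(name = "c", taxid = 55L, genus = "g",
                      genus_taxid = 56L, phylum = "p", phylum_taxid = 57L,
                      genome_size = 3e6, gc = 0.5,
                      mode = "host-associated", mass_per_unit = 1e-3)
  s10 <- expected_read_fractions(d, panel, 0.10)
  s99 <- expected_read_fractions(d, panel, 0.99)
  # hand mass arithmetic: share of total reads = mpu*h / (1 + mpu*h)
  expect_equal(unname(s10["55"]), 1e-4 / (1 + 1e-4), tolerance = 1e-12)
  expect_equal(unname(s99["55"]), 9.9e-4 / (1 + 9.9e-4), tolerance = 1e-12)
  expect_equal(unname(s99["55"] / s10["55"]), 9.9, tolerance = 1e-3)
})

test_that("expected fractions are invariant to rescaling genome copies", {
  d <- build_default_design()
  panel <- default_contaminant_panel()
  p1 <- expected_read_fractions(d, panel, 0.9)
  d2 <- d; d2$members$copies <- d2$members$copies * 137.5
  p2 <- expected_read_fractions(d2, panel, 0.9)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("sample simulation is seeded, conservative and calibrated", {
  cfg <- simulation_config(depth = 1e6, seed = 7)
  s1 <- simulate_sample(cfg, 0.9, seed = 123)
  s2 <- simulate_sample(cfg, 0.9, seed = 123)
  expect_identical(s1$counts, s2$counts)
  expect_equal(sum(s1$counts), cfg$depth)
  # empirical host fraction within 3 binomial SD of its expectation
  p <- expected_read_fractions(cfg$design, cfg$panel, 0.9)
  ph <- unname(p[as.character(cfg$design$host$taxid)])
  obs <- s1$counts[as.character(cfg$design$host$taxid)] / cfg$depth
  expect_lt(abs(obs - ph), 3 * sqrt(ph * (1 - ph) / cfg$depth))
})

test_that("misassignment moves a fraction of the source reads", {
  cfg <- simulation_config(depth = 1e6, seed = 3)
  s <- simulate_sample(cfg, 0, seed = 11)
  art <- c("623", "28901", "546", "573")
  moved <- sum(s$counts[art], na.rm = TRUE)
  src <- s$counts["562"]
  rate_hat <- moved / (moved + src)
  expect_gt(moved, 0)
  # 0.5 % +- 5 binomial SD
  n <- moved + src
  expect_lt(abs(rate_hat - 0.005), 5 * sqrt(0.005 * 0.995 / n))
})

test_that("experiment produces the MS/SSxx dilution series", {
  cfg <- simulation_config(depth = 2e4, seed = 5)
  expt <- simulate_experiment(cfg)
  expect_equal(colnames(expt$profile$counts),
               c("MS", "SS10", "SS90", "SS99"))
  expect_equal(unname(colSums(expt$profile$counts)), rep(2e4, 4))
  expect_equal(unname(expt$profile$samples$host_fraction_nominal),
               c(0, 0.10, 0.90, 0.99))
  # determinism of the whole experiment
  expt2 <- simulate_experiment(cfg)
  expect_identical(expt$profile$counts, expt2$profile$counts)
  # truth labels mark every panel member as a contaminant
  tc <- expt$truth$taxon_class[as.character(cfg$panel$taxid)]
  expect_true(all(tc %in% c("contaminant-host", "contaminant-reagent")))
  expect_equal(sum(expt$truth$taxon_class == "target"), 20)
})

test_that("host-associated expected frequencies fall inversely with the microbial total", {
  # regression on log-log expectations across the spiked samples:
  # a reagent contaminant's slope is exactly -1; a host-associated
  # contaminant falls at least as steeply (its mass also shrinks as the
  # community is diluted away)
  cfg <- simulation_config()
  hf <- c(0.10, 0.90, 0.99)
  p <- lapply(hf, function(h)
    expected_read_fractions(cfg$design, cfg$panel, h))
  host_id <- as.character(cfg$design$host$taxid)
  micro <- vapply(p, function(x) sum(x[setdiff(names(x), host_id)]),
                  numeric(1))
  slope <- function(taxid) {
    f <- vapply(p, function(x) unname(x[taxid]), numeric(1)) / micro
    stats::coef(stats::lm(log10(f) ~ log10(micro)))[[2]]
  }
  rc <- as.character(cfg$panel$taxid[cfg$panel$mode == "reagent-constant"])
  ha <- as.character(cfg$panel$taxid[cfg$panel$mode == "host-associated"])
  for (id in rc[1]) expect_equal(slope(id), -1, tolerance = 1e-2)
  for (id in ha[c(1, 15, 30)]) {
    s <- slope(id)
    expect_lt(s, -1)
    expect_gt(s, -2)
  }
  # and target frequencies stay flat by comparison
  expect_gt(slope(as.character(cfg$design$members$taxid[1])), -0.2)
})

test_that("simulation config round-trips through YAML", {
  cfg <- simulation_config(depth = 5e4, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$design$members, cfg$design$members)
  expect_equal(as.data.frame(back$panel), as.data.frame(cfg$panel))
  expect_equal(back$host_fractions, cfg$host_fractions)
  expect_equal(back$depth, cfg$depth)
  expect_equal(back$seed, cfg$seed)
  # and reproduces the same experiment
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(back)
  expect_identical(e1$profile$counts, e2$profile$counts)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(host_fractions = c(0, 1)), "\\[0, 1\\)")
  expect_error(simulation_config(depth = 0), "depth")
  expect_error(default_confusion_model(rate = 1.2))
})
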