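test_that("kraken report lines parse into direct counts, taxids and ranks", {
  path <- withr::local_tempfile(fileext = ".kreport")
  writeLines(c("100.00\t150\t0\tR\t1\troot",
               "100.00\t150\t50\tG\t561\t  Escherichia",
               " 66.67\t100\t50\tS\t562\t    Escherichia coli",
               " 33.33\t50\t50\tS1\t100562\t      Escherichia coli O157"),
             path)
  r <- read_kraken_report(path)
  expect_equal(unname(r$counts["562"]), 50)
  expect_equal(unname(r$clade["562"]), 100)
  tx <- r$taxonomy
  expect_equal(tx$rank[tx$taxid == 562], "species")
  expect_equal(tx$parent_taxid[tx$taxid == 562], 561)
  # sub-rank codes map to "other" and hang off the species
  expect_equal(tx$rank[tx$taxid == 100562], "other")
  expect_equal(tx$parent_taxid[tx$taxid == 100562], 562)
})

test_that("kraken parser accepts the 8-column minimizer layout", {
  path <- withr::local_tempfile()
  writeLines(c("100.00\t10\t0\t12\t9\tR\t1\troot",
               "100.00\t10\t10\t12\t9\tS\t562\t  Escherichia coli"),
             path)
  r <- read_kraken_report(path)
  expect_equal(unname(r$counts["562"]), 10)
})

test_that("kraken parser rejects malformed input with a line number", {
  path <- withr::local_tempfile()
  writeLines(c("100.00\t10\t0\tR\t1\troot",
               "oops\tnot\tenough"), path)
  expect_error(read_kraken_report(path), "line 2")
  writeLines(c("100.00\t10\t0\tR\t1\troot",
               " 50.00\tx\t5\tS\t562\t  Escherichia coli"), path)
  expect_error(read_kraken_report(path), "line 2.*non-numeric")
  writeLines(c("100.00\t5\t10\tR\t1\troot"), path)
  expect_error(read_kraken_report(path), "clade reads")
})

test_that("empty kraken report yields an empty column", {
  path <- withr::local_tempfile()
  writeLines(character(0), path)
  r <- read_kraken_report(path)
  expect_length(r$counts, 0)
  expect_equal(nrow(r$taxonomy), 0)
})

test_that("kraken report round-trips counts, lineage and ranks", {
  tax <- tiny_taxonomy()
  counts <- c(`1` = 3, `562` = 50, `564` = 7, `623` = 11, `1280` = 20,
              `10090` = 900)
  path <- withr::local_tempfile()
  write_kraken_report(counts, tax, path)
  r <- read_kraken_report(path)
  nz <- r$counts[r$counts > 0]
  expect_equal(nz[order(names(nz))], counts[order(names(counts))])
  # lineage identical for every re-read taxon
  for (id in names(nz)) {
    expect_equal(tax_lineage(r$taxonomy, as.integer(id)),
                 tax_lineage(tax, as.integer(id)))
  }
  ranks_in <- tax$rank[match(as.integer(names(nz)), tax$taxid)]
  ranks_out <- r$taxonomy$rank[match(as.integer(names(nz)),
                                     r$taxonomy$taxid)]
  expect_equal(ranks_out, ranks_in)
  # clade counts on the way out satisfy clade >= direct everywhere
  expect_true(all(r$clade >= r$counts))
})

test_that("bracken output round-trips and validates", {
  tax <- tiny_taxonomy()
  counts <- c(`562` = 120, `1280` = 60, `623` = 20)
  path <- withr::local_tempfile()
  write_bracken_output(counts, tax, path)
  r <- read_bracken_output(path)
  expect_equal(r$counts[order(names(r$counts))],
               counts[order(names(counts))])
  expect_equal(unname(r$counts["1280"]), 60)
  # fractions recomputable within 1e-4
  expect_true(all(abs(r$table$fraction_total_reads -
                        r$counts / sum(r$counts)) < 1e-4))
  # missing header field
  df <- utils::read.delim(path)
  df$new_est_reads <- NULL
  path2 <- withr::local_tempfile()
  utils::write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_bracken_output(path2), "new_est_reads")
})

test_that("bracken fractions summing above 1 warn but keep counts", {
  path <- withr::local_tempfile()
  writeLines(c(paste(BRACKEN_HEADER <- c("name", "taxonomy_id",
                                         "taxonomy_lvl",
                                         "kraken_assigned_reads",
                                         "added_reads", "new_est_reads",
                                         "fraction_total_reads"),
                     collapse = "\t"),
               "Escherichia coli\t562\tS\t100\t0\t100\t0.70000",
               "Staphylococcus aureus\t1280\tS\t100\t0\t100\t0.70000"),
             path)
  w <- capture_warnings(r <- read_bracken_output(path))
  expect_true(any(grepl("exceeds 1", w)))
  expect_true(any(grepl("not recomputable", w)))
  expect_equal(sum(r$counts), 200)
})

test_that("assemble_profile unions taxa, zero-fills and rejects duplicates", {
  tax <- tiny_taxonomy()
  cols <- list(c(`562` = 10), c(`1280` = 5))
  prof <- assemble_profile(cols, tax, sample_meta(c("A", "B")))
  expect_equal(dim(prof$counts), c(2L, 2L))
  expect_equal(prof$counts["562", "B"], 0)
  expect_equal(prof$counts["1280", "A"], 0)
  one <- assemble_profile(cols[1], tax, sample_meta("A"))
  expect_equal(unname(one$counts[, "A"]), unname(cols[[1]]))
  expect_error(assemble_profile(cols, tax, sample_meta(c("A", "A"))),
               "duplicate")
})

test_that("profile TSV round-trips through the long format", {
  tax <- tiny_taxonomy()
  prof <- assemble_profile(list(c(`562` = 10, `623` = 4),
                                c(`1280` = 5, `10090` = 99)),
                           tax, sample_meta(c("A", "B")))
  path <- withr::local_tempfile()
  write_profile_tsv(prof, path)
  back <- read_profile_tsv(path, tax)
  expect_equal(back$counts[rownames(prof$counts), colnames(prof$counts)],
               prof$counts)
})

test_that("aggregation sums congeners into their genus and conserves totals", {
  tax <- tiny_taxonomy()
  prof <- assemble_profile(list(c(`562` = 10, `564` = 5, `623` = 3)),
                           tax, sample_meta("A"))
  gen <- aggregate_at_rank(prof, "genus")
  expect_equal(gen$counts["561", "A"], 15)
  expect_equal(gen$counts["620", "A"], 3)
  expect_equal(colSums(gen$counts), colSums(prof$counts))
  # species-level aggregation of a species-level table is the identity
  sp <- aggregate_at_rank(prof, "species")
  expect_equal(sp$counts[rownames(prof$counts), , drop = FALSE],
               prof$counts)
  expect_error(aggregate_at_rank(prof, "tribe"), "unknown rank")
})

test_that("taxa without an ancestor at the rank pool into the sentinel", {
  tax <- tiny_taxonomy()
  # domain-level reads have no genus ancestor
  prof <- assemble_profile(list(c(`2` = 7, `562` = 3)),
                           tax, sample_meta("A"))
  gen <- aggregate_at_rank(prof, "genus")
  expect_equal(gen$counts["unranked", "A"], 7)
  expect_equal(colSums(gen$counts), colSums(prof$counts))
})

test_that("taxon labels partition and follow the lineage rules", {
  tax <- tiny_taxonomy()
  ids <- as.character(tax$taxid)
  prof <- assemble_profile(
    list(stats::setNames(rep(1, length(ids)), ids)),
    tax, sample_meta("A"))
  lab <- label_taxa(prof, tiny_targets, tiny_host)
  expect_setequal(names(lab), rownames(prof$counts))
  expect_true(all(lab %in% c("target-species", "target-lineage", "host",
                             "off-target", "ambiguous")))
  expect_equal(unname(lab["562"]), "target-species")
  expect_equal(unname(lab["1280"]), "target-species")
  # congeneric sister species and the genus itself are in the lineage
  expect_equal(unname(lab["564"]), "target-lineage")
  expect_equal(unname(lab["561"]), "target-lineage")
  expect_equal(unname(lab["1224"]), "target-lineage")
  # outside the expected genera
  expect_equal(unname(lab["620"]), "off-target")
  expect_equal(unname(lab["623"]), "off-target")
  # host subtree and host-only ancestors
  expect_equal(unname(lab["10090"]), "host")
  expect_equal(unname(lab["10088"]), "host")
  expect_equal(unname(lab["2759"]), "host")
  # shared ancestors are neither host nor microbial
  expect_equal(unname(lab["1"]), "ambiguous")
  expect_equal(unname(lab["131567"]), "ambiguous")
  expect_error(label_taxa(prof, c(562, 999999), tiny_host), "999999")
})

test_that("microbial totals exclude host and shared ancestors", {
  tax <- tiny_taxonomy()
  prof <- assemble_profile(
    list(c(`562` = 10, `623` = 5, `10090` = 90, `1` = 2),
         c(`10090` = 50),
         c(`562` = 7)),
    tax, sample_meta(c("mix", "allhost", "nohost")))
  lab <- label_taxa(prof, tiny_targets, tiny_host)
  tot <- microbial_totals(prof, lab)
  expect_equal(unname(tot["mix"]), 15)
  expect_equal(unname(tot["allhost"]), 0)
  expect_equal(unname(tot["nohost"]), sum(prof$counts[, "nohost"]))
})

test_that("taxonomy TSV round-trips", {
  tax <- tiny_taxonomy()
  path <- withr::local_tempfile()
  write_taxonomy_tsv(tax, path)
  back <- read_taxonomy_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(tax))
})
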