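# Taxon-level simulator of a host spike-in experiment: a staggered mock
# community diluted with increasing proportions of host DNA, plus
# host-associated and reagent contaminants and classifier misassignment.
# Simulation operates on read counts, not sequences: downstream analyses
# concern profile composition only.

# ---- default community -----------------------------------------------------

.default_members <- function() {
  # 20 species in 17 genera; theoretical genome copies staggered over a
  # 2500-fold range. Genome sizes (Mb) and GC are approximate published
  # values for the named organisms.
  m <- read.table(header = TRUE, text = "
name                         taxid  genus          genus_taxid phylum         phylum_taxid copies size_mb gc
Streptococcus_pneumoniae     1313   Streptococcus  1301        Firmicutes     1239         2500   2.04    0.397
Escherichia_coli             562    Escherichia    561         Proteobacteria 1224         40     4.64    0.507
Staphylococcus_aureus        1280   Staphylococcus 1279        Firmicutes     1239         40     2.82    0.328
Bacillus_subtilis            1423   Bacillus       1386        Firmicutes     1239         40     4.22    0.436
Enterococcus_faecalis        1351   Enterococcus   1350        Firmicutes     1239         40     3.36    0.374
Listeria_monocytogenes       1639   Listeria       1637        Firmicutes     1239         10     2.99    0.380
Lactobacillus_fermentum      1613   Lactobacillus  1578        Firmicutes     1239         10     2.10    0.515
Streptococcus_mutans         1309   Streptococcus  1301        Firmicutes     1239         10     2.03    0.368
Staphylococcus_epidermidis   1282   Staphylococcus 1279        Firmicutes     1239         10     2.50    0.321
Bacillus_cereus              1396   Bacillus       1386        Firmicutes     1239         10     5.43    0.354
Acinetobacter_baumannii      470    Acinetobacter  469         Proteobacteria 1224         10     3.98    0.390
Neisseria_meningitidis       487    Neisseria      482         Proteobacteria 1224         10     2.27    0.516
Serratia_marcescens          615    Serratia       613         Proteobacteria 1224         10     5.13    0.597
Bacteroides_fragilis         817    Bacteroides    816         Bacteroidetes  976          2      5.21    0.432
Prevotella_melaninogenica    28132  Prevotella     838         Bacteroidetes  976          2      3.17    0.410
Cutibacterium_acnes          1747   Cutibacterium  1912216     Actinobacteria 201174       2      2.56    0.601
Bifidobacterium_longum       216816 Bifidobacterium 1678       Actinobacteria 201174       2      2.26    0.602
Deinococcus_radiodurans      1299   Deinococcus    1298        Deinococcota   1297         2      3.28    0.670
Schaalia_odontolytica        1660   Schaalia       2529408     Actinobacteria 201174       2      2.39    0.654
Pseudomonas_aeruginosa       287    Pseudomonas    286         Proteobacteria 1224         1      6.26    0.663
", stringsAsFactors = FALSE)
  m$name <- gsub("_", " ", m$name)
  m$genome_size <- m$size_mb * 1e6
  m$size_mb <- NULL
  m
}

# Off-target species that absorb misassigned reads from Escherichia coli.
.artifact_members <- function() {
  a <- read.table(header = TRUE, text = "
name                    taxid  genus       genus_taxid phylum         phylum_taxid size_mb gc
Shigella_flexneri       623    Shigella    620         Proteobacteria 1224         4.60    0.508
Salmonella_enterica     28901  Salmonella  590         Proteobacteria 1224         4.86    0.522
Citrobacter_freundii    546    Citrobacter 544         Proteobacteria 1224         5.10    0.517
Klebsiella_pneumoniae   573    Klebsiella  570         Proteobacteria 1224         5.31    0.573
", stringsAsFactors = FALSE)
  a$name <- gsub("_", " ", a$name)
  a$genome_size <- a$size_mb * 1e6
  a$size_mb <- NULL
  a
}

#' Default spike-in community design
#'
#' Twenty bacterial species in seventeen genera with theoretical genome
#' copies staggered over a 2500-fold range, mixed with a murine host. Read
#' shares are proportional to DNA mass (genome copies x genome size), so
#' the staggering emulates a mock community whose relative abundances span
#' more than three orders of magnitude.
#'
#' @return A `community_design`: list with `members` (data.frame: `name`,
#'   `taxid`, `genus`, `genus_taxid`, `phylum`, `phylum_taxid`, `copies`,
#'   `genome_size` in bp, `gc`) and `host` (list: `name`, `taxid`,
#'   `genome_size`, `gc`).
#' @export
build_default_design <- function() {
  design <- list(members = .default_members(),
                 host = list(name = "Mus musculus", taxid = 10090L,
                             genome_size = 2.7e9, gc = 0.42))
  class(design) <- "community_design"
  validate_design(design)
  design
}

#' @rdname build_default_design
#' @param design A `community_design` to validate.
#' @export
validate_design <- function(design) {
  m <- design$members
  if (nrow(m) < 2) stop("community design needs >= 2 members")
  if (any(m$genome_size <= 0)) stop("genome sizes must be positive")
  if (any(m$gc < 0 | m$gc > 1)) stop("GC fractions must lie in [0,1]")
  if (any(m$copies <= 0)) stop("theoretical genome copies must be positive")
  invisible(design)
}

#' Default contaminant panel
#'
#' Thirty host-associated species (DNA mass proportional to host DNA mass;
#' collectively 0.2 % of it, individual masses log-uniform over two
#' decades) and five reagent species of constant mass per sample. Genus
#' names follow commonly reported kit contaminants; taxids (9xxxxxx range)
#' and genome metadata are synthetic placeholders.
#'
#' @param host_mass_fraction Total host-associated contaminant DNA mass as
#'   a fraction of host DNA mass (default 0.002).
#' @param reagent_mass Total reagent contaminant DNA mass per sample, on
#'   the scale where host plus community mass is 1 (default 2e-4).
#' @return A `contaminant_panel` data.frame with columns `name`, `taxid`,
#'   `genus`, `genus_taxid`, `phylum`, `phylum_taxid`, `genome_size`, `gc`,
#'   `mode` (`host-associated` or `reagent-constant`), `mass_per_unit`.
#' @export
default_contaminant_panel <- function(host_mass_fraction = 0.002,
                                      reagent_mass = 2e-4) {
  ha_genera <- c("Pasteurella", "Halomonas", "Alcanivorax", "Mycobacterium",
                 "Sphingomonas", "Methylobacterium", "Burkholderia",
                 "Cupriavidus", "Pelomonas", "Herbaspirillum", "Acidovorax",
                 "Aquabacterium", "Variovorax", "Comamonas", "Delftia",
                 "Stenotrophomonas", "Xanthomonas", "Phyllobacterium",
                 "Mesorhizobium", "Rhizobium", "Ochrobactrum", "Caulobacter",
                 "Brevundimonas", "Novosphingobium", "Sphingobium",
                 "Sphingopyxis", "Massilia", "Janthinobacterium",
                 "Undibacterium", "Duganella")
  ha_species <- c("Pasteurella multocida", "Halomonas elongata",
                  "Alcanivorax borkumensis", "Mycobacterium smegmatis",
                  "Sphingomonas paucimobilis", "Methylobacterium extorquens",
                  "Burkholderia cepacia", "Cupriavidus metallidurans",
                  "Pelomonas saccharophila", "Herbaspirillum seropedicae",
                  "Acidovorax temperans", "Aquabacterium parvum",
                  "Variovorax paradoxus", "Comamonas testosteroni",
                  "Delftia acidovorans", "Stenotrophomonas maltophilia",
                  "Xanthomonas campestris", "Phyllobacterium myrsinacearum",
                  "Mesorhizobium loti", "Rhizobium leguminosarum",
                  "Ochrobactrum anthropi", "Caulobacter vibrioides",
                  "Brevundimonas diminuta", "Novosphingobium aromaticivorans",
                  "Sphingobium yanoikuyae", "Sphingopyxis alaskensis",
                  "Massilia timonae", "Janthinobacterium lividum",
                  "Undibacterium pigrum", "Duganella zoogloeoides")
  rc_genera <- c("Cronobacter", "Enterobacter", "Nitrosopumilus",
                 "Ralstonia", "Bradyrhizobium")
  rc_species <- c("Cronobacter sakazakii", "Enterobacter cloacae",
                  "Nitrosopumilus maritimus", "Ralstonia pickettii",
                  "Bradyrhizobium japonicum")
  n_ha <- length(ha_species); n_rc <- length(rc_species)
  w_ha <- 10^seq(0, -2, length.out = n_ha)
  w_rc <- 10^seq(0, -1, length.out = n_rc)
  phylum <- rep("Proteobacteria", n_ha + n_rc)
  phylum_taxid <- rep(1224L, n_ha + n_rc)
  phylum[c(4, n_ha + 3)] <- c("Actinobacteria", "Thaumarchaeota")
  phylum_taxid[c(4, n_ha + 3)] <- c(201174L, 651137L)
  panel <- data.frame(
    name = c(ha_species, rc_species),
    taxid = c(9000001L + seq_len(n_ha) - 1L,
              9000501L + seq_len(n_rc) - 1L),
    genus = c(ha_genera, rc_genera),
    genus_taxid = c(9100001L + seq_len(n_ha) - 1L,
                    9100501L + seq_len(n_rc) - 1L),
    phylum = phylum, phylum_taxid = phylum_taxid,
    genome_size = round(seq(2.2e6, 6.8e6,
                            length.out = n_ha + n_rc)),
    gc = round(seq(0.32, 0.68, length.out = n_ha + n_rc), 3),
    mode = rep(c("host-associated", "reagent-constant"), c(n_ha, n_rc)),
    mass_per_unit = c(host_mass_fraction * w_ha / sum(w_ha),
                      reagent_mass * w_rc / sum(w_rc)),
    stringsAsFactors = FALSE)
  class(panel) <- c("contaminant_panel", "data.frame")
  panel
}

#' Default classifier confusion model
#'
#' The Escherichia coli member misassigns a small fraction of its reads,
#' split evenly across four sister-genus species (Shigella, Salmonella,
#' Citrobacter, Klebsiella), emulating k-mer misclassification among
#' closely related Enterobacteriaceae. All other taxa assign cleanly.
#'
#' @param rate Total misassigned fraction of the source's reads
#'   (default 0.005).
#' @return A `confusion_model`: named list (by source taxid) of data.frames
#'   with columns `taxid` (assigned) and `p`; each row-sum of `p` is 1.
#' @export
default_confusion_model <- function(rate = 0.005) {
  stopifnot(rate >= 0, rate < 1)
  art <- .artifact_members()
  rows <- list(`562` = data.frame(
    taxid = c(562L, art$taxid),
    p = c(1 - rate, rep(rate / nrow(art), nrow(art)))))
  class(rows) <- "confusion_model"
  validate_confusion(rows)
  rows
}

#' @rdname default_confusion_model
#' @param confusion A `confusion_model` to validate (row-stochastic,
#'   non-negative).
#' @export
validate_confusion <- function(confusion) {
  for (src in names(confusion)) {
    row <- confusion[[src]]
    if (any(row$p < 0)) stop("negative confusion probability for ", src)
    if (abs(sum(row$p) - 1) > 1e-9)
      stop("confusion probabilities for ", src, " do not sum to 1")
  }
  invisible(confusion)
}

#' Synthetic taxonomy for a simulated experiment
#'
#' Builds the taxonomic tree (root, cellular organisms, domains, phyla,
#' genera, species and the host lineage) covering a community design, its
#' contaminant panel and the misassignment artifact species.
#'
#' @param design A `community_design`.
#' @param panel A `contaminant_panel`.
#' @return A [taxonomy()].
#' @export
build_design_taxonomy <- function(design = build_default_design(),
                                  panel = default_contaminant_panel()) {
  base <- data.frame(
    taxid = c(1L, 131567L, 2L, 2157L, 2759L,
              7711L, 40674L, 10066L, 10088L),
    parent_taxid = c(NA, 1L, 131567L, 131567L, 131567L,
                     2759L, 7711L, 40674L, 10066L),
    rank = c("other", "other", "domain", "domain", "domain",
             "phylum", "class", "family", "genus"),
    name = c("root", "cellular organisms", "Bacteria", "Archaea",
             "Eukaryota", "Chordata", "Mammalia", "Muridae", "Mus"),
    stringsAsFactors = FALSE)
  host <- data.frame(taxid = design$host$taxid, parent_taxid = 10088L,
                     rank = "species", name = design$host$name)
  sp <- rbind(design$members[, c("taxid", "genus_taxid", "name")],
              as.data.frame(panel)[, c("taxid", "genus_taxid", "name")],
              .artifact_members()[, c("taxid", "genus_taxid", "name")])
  genera <- unique(rbind(
    design$members[, c("genus_taxid", "phylum_taxid", "genus")],
    panel[, c("genus_taxid", "phylum_taxid", "genus")],
    .artifact_members()[, c("genus_taxid", "phylum_taxid", "genus")]))
  phyla <- unique(rbind(
    design$members[, c("phylum_taxid", "phylum")],
    panel[, c("phylum_taxid", "phylum")],
    .artifact_members()[, c("phylum_taxid", "phylum")]))
  # archaeal phyla sit under Archaea, the rest under Bacteria
  phyla$parent <- ifelse(phyla$phylum_taxid == 651137L, 2157L, 2L)
  nodes <- rbind(
    base,
    data.frame(taxid = phyla$phylum_taxid, parent_taxid = phyla$parent,
               rank = "phylum", name = phyla$phylum),
    data.frame(taxid = genera$genus_taxid, parent_taxid = genera$phylum_taxid,
               rank = "genus", name = genera$genus),
    data.frame(taxid = sp$taxid, parent_taxid = sp$genus_taxid,
               rank = "species", name = sp$name),
    host)
  taxonomy(nodes$taxid, nodes$parent_taxid, nodes$rank, nodes$name)
}

# ---- configuration ---------------------------------------------------------

#' Simulation configuration
#'
#' @param design A `community_design` ([build_default_design()]).
#' @param panel A `contaminant_panel` ([default_contaminant_panel()]).
#' @param confusion A `confusion_model` ([default_confusion_model()]).
#' @param tax Taxonomy covering all taxa; built with
#'   [build_design_taxonomy()] when `NULL`.
#' @param host_fractions Host DNA proportions of total DNA mass, each in
#'   \[0, 1); defaults to the 0/10/90/99 % dilution series.
#' @param depth Reads per sample (default 1e6).
#' @param seed Master integer seed; per-sample seeds are
#'   `(100 * seed + sample index) mod (2^31 - 1)`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = build_default_design(),
                              panel = default_contaminant_panel(),
                              confusion = default_confusion_model(),
                              tax = NULL,
                              host_fractions = c(0, 0.10, 0.90, 0.99),
                              depth = 1e6, seed = 1L) {
  validate_design(design)
  validate_confusion(confusion)
  if (any(host_fractions < 0 | host_fractions >= 1))
    stop("host fractions must lie in [0, 1)")
  if (depth <= 0) stop("depth must be positive")
  if (!all(panel$mode %in% c("host-associated", "reagent-constant")))
    stop("unknown contaminant mode")
  if (is.null(tax)) tax <- build_design_taxonomy(design, panel)
  structure(list(design = design, panel = panel, confusion = confusion,
                 taxonomy = tax, host_fractions = host_fractions,
                 depth = depth, seed = as.integer(seed)),
            class = "simulation_config")
}

.derive_seed <- function(master, i) {
  as.integer((abs(as.numeric(master)) * 100 + i) %% (2^31 - 1))
}

# ---- expectation and sampling ----------------------------------------------

#' Expected read fractions under the DNA-mass mixing model
#'
#' Mixing is by DNA mass: community members contribute mass proportional to
#' genome copies x genome size, rescaled so the community carries
#' `1 - host_fraction` and the host `host_fraction` of the (pre-contaminant)
#' mass. Host-associated contaminants carry `mass_per_unit` per unit host
#' mass; reagent contaminants a constant `mass_per_unit` per sample. Read
#' fractions are the normalized masses.
#'
#' @param design A `community_design`.
#' @param panel A `contaminant_panel` (may have zero rows).
#' @param host_fraction Host proportion of total DNA mass, in \[0, 1).
#' @return Named numeric vector of proportions (names are taxids: members,
#'   host, contaminants), summing to 1.
#' @export
expected_read_fractions <- function(design, panel, host_fraction) {
  if (host_fraction < 0 || host_fraction >= 1)
    stop("host_fraction must lie in [0, 1)")
  m <- design$members
  w <- m$copies * m$genome_size
  mass <- c(stats::setNames((1 - host_fraction) * w / sum(w),
                            as.character(m$taxid)),
            stats::setNames(host_fraction, as.character(design$host$taxid)))
  if (nrow(panel)) {
    cm <- ifelse(panel$mode == "host-associated",
                 panel$mass_per_unit * host_fraction,
                 panel$mass_per_unit)
    mass <- c(mass, stats::setNames(cm, as.character(panel$taxid)))
  }
  mass / sum(mass)
}

#' Simulate one sample
#'
#' A single multinomial draw of `depth` reads over the expected read
#' fractions, followed by per-source multinomial reallocation through the
#' confusion model. Identical seeds give identical counts.
#'
#' @param config A [simulation_config()].
#' @param host_fraction Host proportion for this sample.
#' @param seed Integer seed for this sample.
#' @return List with `counts` (named numeric over member, host, contaminant
#'   and artifact taxids; sums to `depth`).
#' @export
simulate_sample <- function(config, host_fraction, seed) {
  p <- expected_read_fractions(config$design, config$panel, host_fraction)
  if (all(p == 0)) stop("degenerate expected fractions: all zero")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- stats::setNames(as.numeric(
    stats::rmultinom(1, size = config$depth, prob = p)), names(p))
  for (src in names(config$confusion)) {
    n <- counts[src]
    if (is.na(n) || n == 0) next
    row <- config$confusion[[src]]
    moved <- stats::setNames(as.numeric(
      stats::rmultinom(1, size = n, prob = row$p)),
      as.character(row$taxid))
    counts[src] <- 0
    for (dst in names(moved)) {
      counts[dst] <- (if (is.na(counts[dst])) 0 else counts[dst]) + moved[dst]
    }
  }
  list(counts = counts)
}

#' Simulate the full dilution-series experiment
#'
#' One sample per host fraction, labelled by the MS/SSxx convention
#' (MS for 0 % host, SS10/SS90/SS99 for 10/90/99 %). Per-sample seeds are
#' derived deterministically from the master seed.
#'
#' @param config A [simulation_config()].
#' @return List with `profile` (a [profile_table()]) and `truth`
#'   (ground-truth labels: `taxon_class`, a named character vector over all
#'   simulated taxa with values in `target`, `host`, `contaminant-host`,
#'   `contaminant-reagent`, `misassignment-artifact`; and `host_fraction`,
#'   named per sample).
#' @export
simulate_experiment <- function(config) {
  hf <- config$host_fractions
  labels <- ifelse(hf == 0, "MS", paste0("SS", round(100 * hf)))
  cols <- vector("list", length(hf))
  for (i in seq_along(hf)) {
    cols[[i]] <- simulate_sample(config, hf[i],
                                 .derive_seed(config$seed, i))$counts
  }
  meta <- sample_meta(labels, host_fraction_nominal = hf,
                      total_reads = config$depth)
  profile <- assemble_profile(cols, config$taxonomy, meta)
  art <- .artifact_members()
  truth_class <- c(
    stats::setNames(rep("target", nrow(config$design$members)),
                    as.character(config$design$members$taxid)),
    stats::setNames("host", as.character(config$design$host$taxid)),
    stats::setNames(ifelse(config$panel$mode == "host-associated",
                           "contaminant-host", "contaminant-reagent"),
                    as.character(config$panel$taxid)),
    stats::setNames(rep("misassignment-artifact", nrow(art)),
                    as.character(art$taxid)))
  list(profile = profile,
       truth = list(taxon_class = truth_class,
                    host_fraction = stats::setNames(hf, labels)))
}

# ---- config serialization --------------------------------------------------

#' Write / read a simulation configuration file
#'
#' YAML serialization of the full configuration (community members,
#' contaminant panel, confusion rows, host fractions, depth, seed) so a
#' simulated experiment can be reproduced from a single text file.
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a [simulation_config()].
#' @export
write_sim_config <- function(config, path) {
  obj <- list(
    host = config$design$host,
    members = lapply(as.data.frame(config$design$members), as.vector),
    panel = lapply(as.data.frame(config$panel), as.vector),
    confusion = lapply(unclass(config$confusion),
                       function(r) lapply(as.data.frame(r), as.vector)),
    host_fractions = config$host_fractions,
    depth = config$depth, seed = config$seed)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  design <- structure(list(
    members = as.data.frame(obj$members, stringsAsFactors = FALSE),
    host = obj$host), class = "community_design")
  panel <- as.data.frame(obj$panel, stringsAsFactors = FALSE)
  class(panel) <- c("contaminant_panel", "data.frame")
  confusion <- lapply(obj$confusion, function(r)
    as.data.frame(r, stringsAsFactors = FALSE))
  class(confusion) <- "confusion_model"
  simulation_config(design = design, panel = panel, confusion = confusion,
                    host_fractions = as.numeric(obj$host_fractions),
                    depth = obj$depth, seed = obj$seed)
}
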