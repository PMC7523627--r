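# spikeval

Evaluation of shotgun-metagenomic taxonomic profiles as host DNA
increasingly dominates a sample.

When a mock (spike-in) microbial community is diluted with 10 %, 90 % and
99 % host DNA and sequenced to fixed depth, the microbial read count falls
a hundred-fold while constant-mass contaminants keep their absolute
counts — so contamination comes to dominate exactly when microbial signal
is scarcest. `spikeval` implements the analyses needed to quantify this
on profiles produced by read-binning classifiers, plus a taxon-level
simulator of the underlying experiment so everything runs at desk scale:

* **Profile I/O and taxonomy** — native readers/writers for Kraken 2
  reports (lineage reconstructed from the indentation, no taxonomy dump
  needed) and Bracken species outputs; rank aggregation with exact
  count conservation; labelling of every taxon as target species, target
  lineage, host, or off-target.
* **Abundance accuracy** — genome-size normalization
  `abundance_i ∝ count_i / size_i`, observed/expected ratios against the
  theoretical composition, the two-fold band `[0.5, 2]`, mean squared
  relative error `mean(((obs − exp)/exp)²)`, and the GC–ratio Pearson
  correlation.
* **Off-target classification** — genera are synthetic-associated
  (`MS > 10 × SS99` reads), host-associated (`SS99 > 10 × MS`) or
  non-specific, with strict inequalities at the threshold.
* **Frequency-based contaminant identification** — for each species, its
  frequency `f` among microbial reads is regressed on the total microbial
  read count `C` (the DNA-concentration proxy) in log₁₀–log₁₀ space: a
  contaminant model with slope fixed at −1 versus a constant model, both
  intercepts by least squares; the score is the F(n−1, n−1) survival
  function at `SSE_non / SSE_cont`, near 0 for contaminants. Called
  species are removed and removal statistics reported.
* **Simulator** — a 20-species community (theoretical genome copies
  staggered 2500-fold), DNA-mass mixing with a murine host at
  0/10/90/99 %, 30 host-associated plus 5 reagent contaminants, and a
  confusion model that misassigns 0.5 % of Escherichia coli reads to four
  sister genera. Fully seeded and serializable to YAML.

## Worked example

```r
library(spikeval)

cfg <- simulation_config(depth = 1e6, seed = 1)   # MS/SS10/SS90/SS99
report <- run_pipeline(pipeline_config("simulate", sim = cfg))

report$detection$n_detected
#>   MS SS10 SS90 SS99
#>   20   20   20   20

sapply(report$accuracy, `[[`, "mse")
#>           MS         SS10         SS90         SS99
#> 0.0002926575 0.0005867043 0.0025757263 0.0569740066
```

Running the same experiment through the numbered analysis drivers prints
the stage narratives (`Rscript analysis/01_simulate.R 1`, then stages
02–04):

```
  MS: 20/20 species detected, mse 0.0002927, 20/20 within 2-fold
  SS99: 20/20 species detected, mse 0.05697, 19/20 within 2-fold
off-target genera classified: 39 (host-associated 30, non-specific 5,
  synthetic-associated 4)
off-target fraction of microbial reads: MS 0.000372, SS10 0.000575,
  SS90 0.0194, SS99 0.186
10 species called contaminant at threshold 0.1
target species called contaminant: 0
```

Read: every community member — including the rarest, 2500-fold below the
most abundant — is detected even at 99 % host DNA; the pure-community
abundance estimate is accurate to sampling error (MSE ~3×10⁻⁴) and
degrades as host DNA dilutes the community; all 30 planted host-associated
contaminants are recognized from the dilution series; the frequency test
removes contaminants without ever calling a true community member.

## Repository layout

```
R/                  package code (I/O, taxonomy, simulator, abundance,
                    off-target, frequency test, orchestrator)
analysis/           numbered stage drivers writing results/analysis/
scripts/acceptance.R  end-to-end recomputation, JSON output
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette
```
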