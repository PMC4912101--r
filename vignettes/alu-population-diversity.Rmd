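---
title: "Gene diversity and population structure from Alu insertion/deletion markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene diversity and population structure from Alu insertion/deletion markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alupopdiv)
```

## The markers and the model

Polymorphic Alu elements are ~300 bp SINE retrotransposons. A polymorphic
Alu locus is biallelic — the insertion is present (+) or absent (−) — and,
because an element is essentially never excised precisely and the same
site is essentially never hit twice, the ancestral state is known
(absence) and recurrent mutation is negligible. That makes these loci
clean material for classical gene-diversity analysis: a diploid individual
is `II` (+/+), `ID` (+/−) or `DD` (−/−), and everything downstream is a
function of the insertion frequency `p` per population and locus.

`alupopdiv` implements the analysis sequence used in surveys of
structured human populations (the bundled example data come from a survey
of twelve endogamous caste and tribal groups of South India typed at the
seven classical loci ACE, TPA25, FXIIIB, CD4, APO, D1, PV92):

1. allele frequencies by direct counting, `p = (2 n_II + n_ID) / 2n`;
2. observed (`n_ID / n`) and expected (`2pq`) heterozygosity per cell,
   averaged over loci per population;
3. a Hardy–Weinberg χ² goodness-of-fit test per cell with Bonferroni
   correction across the scan;
4. Nei's gene-diversity decomposition per locus across populations:
   `Hs = mean_j 2 p_j q_j`, `Ht = 2 p̄ q̄`, `Gst = (Ht − Hs)/Ht`;
5. genetic distances between populations and a neighbor-joining tree;
6. PCA of the population × locus frequency matrix.

## Reading and counting genotypes

Genotype data travel as plain TSV with columns `population`,
`individual`, `locus`, `genotype`; tokens `"+/+"`, `"+/-"`, `"-/-"` and
`"II"`, `"ID"`, `"DD"` are interchangeable, and the missing code (default
`"NA"`) removes a call from that cell's `n` — direct counting is
complete-case counting, there is no imputation. `read_genotype_table()`
sorts population and locus labels so results never depend on file row
order.

Frequency matrices (for re-analysis of published tables) store only the
insertion frequency; the deletion frequency is always derived as `1 − p`,
which prevents the internal inconsistencies that creep into published
tables where the two rows are rounded or typeset independently. Sample
sizes are carried per locus, not per population, because published typed
counts can differ between loci and between tables for the same group
(the bundled tribal data are one example: 57 typed vs 58 sampled for one
population).

## Heterozygosity conventions

In the bundled published tables the per-locus bold "heterozygosity"
values are *observed* heterozygosity (`n_ID / n`) and the middle "+/−"
rows are *expected* `2pq` of the flanking allele frequencies — the only
reading consistent with the arithmetic (e.g. 2 × 0.7959 × 0.2040 =
0.3247). `heterozygosity_table()` therefore defaults to the observed
series and exposes `series = "expected"`; multi-locus averages are plain
unweighted means over loci. The small-sample factor `2n/(2n−1)` is
available behind `unbiased = TRUE` but off by default, because the
published values match plain `2pq`. Two published cells remain
internally suspect (one observed value equal to the allele frequency,
one above the expected-series bound); the package reports both series and
does not attempt to reproduce individual anomalous cells.

```{r het}
f <- alu_tribal_freqs()
expected_heterozygosity(f["Kani", "TPA25"])
het <- alu_population_het()
average_heterozygosity(unlist(het[het$population == "Kani",
                                  c("ACE", "TPA25", "FXIIIB", "CD4",
                                    "APO", "D1", "PV92")]))
```

## Hardy–Weinberg testing

`hwe_test()` is the plain χ² goodness-of-fit over the three genotype
classes at the fitted frequency, 1 df, no continuity correction — the
test named by the study design. A Levene–Haldane exact test
(`method = "exact"`) is available for small cells. Monomorphic cells have
no test; they are flagged, skipped, and excluded from the Bonferroni
family. The family defaults to every testable cell in one scan
(`family = "run"`), configurable to per-locus families; the published
analysis does not state its family, so the choice is surfaced rather
than hidden.

## Nei's decomposition and the multi-locus convention

`Hs` is the *unweighted* mean of within-population diversities: the
published per-locus identities hold without sample sizes, and the
external comparison groups' sizes are not published, so unweighted is
both what reproduces the tables and the only universally computable
choice. An `n`-weighted variant exists via `weights =`.

Multi-locus aggregation defaults to `"mean-of-ratios"`: `Ht_all`,
`Hs_all`, `Gst_all` are unweighted means of the per-locus values. Every
published "all loci" row in the bundled tables is reproduced by this rule
and none by Nei's classical ratio-of-means, which is nevertheless
provided (`convention = "ratio-of-means"`) and tagged in all outputs.
Loci fixed for the same allele everywhere (`Ht = 0`) have undefined Gst
and are excluded from aggregation with a warning rather than averaged in
as zero.

```{r gst}
study <- alu_study_diversity()
gst_from_ht_hs(0.4959, 0.4664)                       # one locus
multilocus_diversity(study$per_locus)$Gst_all         # all loci
```

Three published diversity rows violate the `(Ht − Hs)/Ht` identity
(printed `Hs > Ht`, or a Gst two orders off the identity) — presumably
transposition typos. They are flagged `identity_ok = FALSE` in the
bundled data and are not reproduction targets.

## Distances and neighbor joining

The study design names the NJ method but not its distance, so the
distance is explicit configuration: Nei's (1972) standard distance
(default) or Da (1983), both computed from the biallelic frequencies and
surfaced in output metadata. `neighbor_joining()` is the standard
Q-criterion agglomeration with rate-corrected branch lengths; exact ties
take the lexicographically smallest index pair, so runs are
deterministic. On additive matrices it recovers the generating topology
and path lengths exactly (a property the test suite exercises on random
trees, alongside a cross-check against an independent NJ
implementation). On non-additive inputs a negative branch length can
arise; it is clamped to zero with the deficit moved to its sibling so
the joined pair's distance is preserved and the Newick output stays
well-formed, with a warning. Published tree figures that depend on
external populations' unpublished frequencies are qualitative context,
not reproduction targets.

## PCA

`pca_frequencies()` centres the raw frequency matrix (no unit-variance
scaling by default — the analysis is of raw allele frequencies; a
`scale` flag exists for sensitivity analysis) and decomposes by SVD.
Variance fractions cover all non-trivial components and sum to 1; each
loading vector is flipped so its largest-magnitude entry is positive,
making score signs platform-stable. The published percentage pair for
the first two components of the 48-population comparison depends on 36
external populations whose frequencies are not published, so PCA
correctness is asserted by properties (eigen-oracle agreement, rotation
invariance, reconstruction) rather than by those two numbers.

## The simulator: what it emulates and what it does not

`simulate_dataset()` draws a Balding–Nichols island model: per locus an
ancestral frequency `p0 ~ U(0.1, 0.9)` (keeping loci informatively
polymorphic, like the moderate-frequency Alu markers), then each of `K`
populations gets `p_j ~ Beta(p0(1−fst)/fst, (1−p0)(1−fst)/fst)`, so the
between-population variance is exactly `fst · p0(1−p0)` and `fst` is the
Gst estimand; genotypes are Hardy–Weinberg draws within populations,
loci independent. This gives every pipeline stage a ground truth: Gst
recovery, HWE type-I calibration, and schema compatibility are all
testable without external data.

What it does not emulate: linkage between loci, ascertainment of
markers, genotyping error, within-population substructure or inbreeding,
and the finite-`K` downward bias of Gst relative to `fst` (of order
`1 − 1/K`, tolerated inside the recovery band rather than corrected).
Passing recovery tests therefore shows the estimator chain is coherent
under the model's assumptions, not that real endogamous populations
satisfy them.

Problem sizes used in the validation suite: recovery runs use `K = 20`
populations, `L = 50` loci, `n = 100` diploids over 100 seeds (estimates
expected in `[0.07, 0.13]` for `fst = 0.10`); HWE calibration uses 10⁴
simulated cells at `n = 100`, `p = 0.3`; NJ consistency uses 100 random
5–10 leaf trees. These sizes make the suite's Monte-Carlo bands tight
enough to be meaningful while keeping a full run fast on one CPU.

## Pipeline

`run_pipeline()` chains the stages (stats → gst → tree → pca) from a
genotype table or directly from a frequency matrix — frequencies-only
mode is first-class because comparative re-analyses start from published
frequency tables, not genotypes. Each run writes TSV/Newick artifacts
plus `manifest.json` recording inputs, resolved flags and collected
warnings; outputs carry no timestamps, so a rerun of the same
configuration is byte-identical and a manifest fully determines its
outputs.

```{r pipeline, eval = FALSE}
cfg <- sim_config(K = 12, L = 7, n = 50, fst = 0.036, seed = 1)
ds <- simulate_dataset(cfg)
write_simulated_dataset(ds, "sim")
run_pipeline(genotypes = "sim/genotypes.tsv", out_dir = "run1")
```

## Numerical notes

* Monomorphic cells: undefined frequencies/tests are errors or flagged
  skips, never silent zeros.
* `nei_distance()` clamps the tiny negative logarithm that floating
  rounding can produce for identical profiles to exactly 0; identical
  fixation at opposite alleles makes the Nei distance infinite and is
  reported as an error naming the pair.
* Published `p` and `q` are rounded independently; functions accept an
  explicit `q` so published arithmetic can be reproduced at printed
  precision.
* PCA drops components whose variance is below `1e-12` of the leading
  one (numerically null directions from centring).
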