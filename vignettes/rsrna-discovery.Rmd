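---
title: "Discovering regulatory small RNAs beyond canonical miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering regulatory small RNAs beyond canonical miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsrnakit)
```

## The problem and the model

Canonical miRNA discovery pipelines require a stem-loop precursor and
therefore discard small RNAs that act like miRNAs without being born like
them. The working model of this package is evidential rather than
structural: a ~17–28 nt RNA is a credible regulator when several
independent layers of evidence converge —

* **recurrence**: it is seen repeatedly within an experimental condition
  (≥ 5 reads) and across conditions (≥ 2), which makes a random degradation
  product unlikely;
* **targeting**: it has a plausible binding site in a transcript, called by
  two independent prediction principles (seed complementarity and
  near-full duplex complementarity) that must agree;
* **physical interaction**: the site is covered by an Argonaute CLIP peak
  while the sRNA itself is present in that Argonaute's bound reads, or a
  CLASH chimeric read ligates the sRNA directly to a fragment of its
  target;
* **differential behavior**: its abundance distinguishes tumor from normal
  states (two-fold RPM change in at least one condition);
* **repression**: its expression anti-correlates with the target's
  transcript or protein level (Pearson r ≤ −0.5, p ≤ 0.05).

Candidates passing all conjunctive clauses are reported as potential
rsRNAs; the remaining layers — biogenesis dependence, hairpin/motif
analysis, genomic annotation — characterize them without filtering.

## Parameters that matter

All thresholds live in `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 5 | reads required within one condition (summed over its samples) |
| `min_conditions` | 2 | distinct conditions with ≥ 1 read |
| `max_genome_mismatches` | 2 | substitutions tolerated in genome alignment (no indels) |
| `max_duplex_mismatches` | 2 | substitutions tolerated in the sRNA:target duplex |
| `flank_bp` | 100 | context on each side of a candidate for hairpin/motif analysis |
| `fold_change_min` | 2.0 | tumor/normal RPM ratio (either direction) |
| `pcc_max`, `p_max` | −0.5, 0.05 | anti-correlation thresholds |
| `pseudocount` | 0.5 | added to both RPM means in fold changes |
| `cnnc_center` ± `cnnc_tolerance` | 17 ± 2 nt | CNNC offset downstream of the precursor 3' end |
| `basal_u_pos`, `basal_g_pos` | −14, −13 | basal U/G offsets upstream of the precursor 5' end |
| `min_stem_pairs`, `min_loop_nt` | 16, 3 | hairpin acceptance |
| `stem_tolerance_nt` | 2 | sRNA bases allowed outside a hairpin arm ("almost perfectly within the stem") |
| `clash_slop_nt` | 25 | slop around a site when matching CLASH fragments |

Decisions where the design was genuinely open, and how this package
resolves them:

* **"More than five times" vs "at least five reads".** The two plausible
  readings differ by one read; the filter uses `count ≥ min_reads` with
  `min_reads = 5`, configurable.
* **Abundance is summed within a condition**, not per sample: "experiment"
  is read as experimental condition, and presence in a condition means one
  read or more.
* **Multi-mapping.** A sequence is counted once in the expression matrix
  regardless of its number of genomic loci; per-locus attribution happens
  only in annotation. Expression is a property of the sequence; loci are a
  property of the genome.
* **G:U wobble** counts as a mismatch in the duplex predictor (a stricter
  reading; a wobble allowance is configurable in principle through the
  mismatch budget).
* **AGO support is a conjunction** (peak overlap *and* read-set presence).
  A disjunction mode exists (`clip_support(mode = "disjunction")`) because
  the looser reading is also defensible.
* **Known-miRNA exclusion is exact-match** by default (`max_mm = 0`),
  configurable.
* **RPM uses the full library** as denominator, including reads that the
  known-miRNA filter later removes — normalization reflects sequencing
  depth, not downstream filtering.
* **The ±100 bp hairpin window spans the sRNA**: `[start − 100, end + 100]`
  rather than ±100 around the start point alone, so 3'-arm candidates keep
  their upstream arm in view.
* **Annotation is sense-matched for gene-derived classes.** An sRNA locus
  counts as exonic/ncRNA/intronic origin only on the host gene's strand;
  repeat and TAR overlaps are strand-agnostic. The reason is structural:
  any target site within the duplex mismatch budget is, by construction,
  also a genomic alignment hit of the sRNA on the opposite strand of the
  target's exon. Treating that antisense binding site as an "exonic
  origin" would let the priority rule (exon first) misclassify essentially
  every sRNA with a strong target site. Sense-matching keeps origin
  assignment meaningful, and the antisense phenomenon itself is captured
  explicitly by `detect_antisense_origin()`.
* **Dependence calls.** "Totally absent in knockdown" is encoded literally
  as zero knockdown reads (`kd_max = 0`, configurable for noisy data);
  `dependent` further requires wild-type evidence (≥ `min_reads`) and, when
  a CLIP set is supplied, at least one CLIP read.

## The hairpin detector

`detect_hairpin()` is a purpose-built single-stem maximizer, not a
free-energy folder: over all choices of precursor and loop it maximizes the
number of nested Watson–Crick/G:U pairs along one stem, with bulges free
and no multiloops, subject to a loop of ≥ `min_loop_nt`. The optimum is
computed by an O(n²) dynamic program over (prefix, suffix) arm pairs whose
row recurrence collapses to a running maximum; ties are broken toward the
shorter, then leftmost precursor by preferring pair moves during traceback.
The choice is deliberate: the quantity the cascade needs ("is there a stem
of ≥ 16 pairs, and does the sRNA sit in an arm?") is combinatorial, and a
combinatorial definition is exactly testable — the test suite and the
acceptance script verify the maximizer against an independent
no-bifurcation Nussinov recursion on hundreds of random windows. A
thermodynamic backend could be substituted without changing the contract,
but would trade oracle-testability for an energy model the cascade never
consults. Note the maximizer is an optimum, not a uniqueness claim: random
200-nt windows frequently contain 16 pairable positions, so
`hairpin_found` alone is weak evidence; the informative flags are stem
placement and the positional motifs.

Motif offsets are anchored on the *detected* precursor: CNNC must start
17 ± 2 nt downstream of the precursor 3' end (first downstream base =
offset 1), basal U and G sit at offsets −14/−13 upstream of the 5' end,
and UGU/GUG must fall inside the loop. Insufficient flank yields
indeterminate (`NA`) flags with a warning, never an error.

## What the synthetic study emulates

`simulate_bundle()` generates, from one seed, a single-chromosome genome
with two-exon genes (introns, UTRs, CDS on both strands), mutated copies of
per-family repeat consensi with recorded `(consensus_offset, orientation)`,
hairpin loci embedding a perfect stem with all three Microprocessor motifs,
and an ncRNA catalog. It then plants rsRNAs of every origin class with
full-complement target sites written into 3' UTRs, assigns biogenesis
labels (hairpin plants Microprocessor-dependent, intron/ncRNA plants
Dicer-only, repeat plants independent), and simulates:

* **counts**: negative-binomial with mean 50 and size 10 per sample
  (4 conditions × tumor/normal × 3 samples), planted fold change 4× —
  `noiseless_counts = TRUE` replaces draws with exact means for
  perfect-recovery checks;
* **decoys**, one per failure mode: too few reads in every condition,
  abundant in a single condition only, duplicates of known miRNAs, and
  fully expressed candidates with target sites but no interaction
  evidence;
* **a stable abundant background** (15 sequences at mean 1000/sample in
  both states) emulating the dominant miRNA/housekeeping fraction of real
  libraries. This matters quantitatively: without a stable majority
  fraction, planted up-in-tumor sRNAs themselves inflate tumor library
  sizes and RPM fold changes shrink toward 1 — a composition effect real
  sRNA libraries largely avoid because most of their mass does not change
  between states;
* **interaction data**: peaks in two Argonautes over every planted site
  (with the sRNA in those read sets) plus a CLASH chimera; background
  peaks and chimeras that match nothing;
* **perturbation read sets** implementing knockdown exclusivity exactly;
* **expression**: each planted target is a decreasing affine function of
  its sRNA's RPM plus Gaussian noise calibrated from
  `sd_noise = slope · sd(x) · sqrt(1/r² − 1)` so the realized Pearson r
  concentrates at the configured −0.8; all other genes are independent
  log-normals.

What it does *not* emulate: sequencing error, adapters, PCR duplicates,
isomiR heterogeneity, realistic chromosome structure, or biological
between-replicate variance beyond the negative binomial. Passing the
recovery tests therefore demonstrates that the cascade's logic is correct
and calibrated under its stated assumptions — not that those assumptions
capture every failure mode of real libraries.

Problem sizes used throughout (tests and the acceptance script): a 60 kb
genome, 30 protein-coding genes, 20 planted rsRNAs, 20 decoys, 24 samples;
oracle comparisons run on 100+ seeded instances per operation (reads vs a
2 kb genome, 120 nt UTRs, 40–60 nt hairpin windows, universes ≤ 200
genes). The reduced-scale fixture used by unit tests keeps the same
structure at 18 genes and 12 planted rsRNAs.

## Numerical choices and degenerate inputs

* Correlation significance uses the two-sided t approximation with
  `n − 2` degrees of freedom; |r| = 1 reports p = 0. Fewer than 3 complete
  pairs or zero variance is an error at the primitive level and an `NA`
  row with a reason in table-level reports.
* Welch's t-test delegates to `stats::t.test`; identical constant groups
  (which `t.test` refuses) are defined as t = 0, p = 1.
* Fold changes add a 0.5 pseudocount to both means, so zero-expression
  states stay finite; the published worked value 20.5/10.5 ≈ 1.95 < 2
  illustrates that the pseudocount can decide borderline calls.
* Enrichment uses the upper-tail hypergeometric `P(X ≥ overlap)` with
  Bonferroni correction (Benjamini–Hochberg is reserved for the
  per-position repeat-profile tests, where hundreds of positions are
  tested jointly).
* Percentages are reported with `round(…, 2)` (round-half-even). Reported
  correlations are rounded to 2 decimals; full precision is retained in
  the `r` column.
* All genomic coordinates are 0-based half-open internally; GFF3 is
  converted on ingest and restored on write. Abutting intervals do not
  overlap.
* Sequences are handled in the DNA alphabet (U→T on ingest, restorable on
  output).

## Known limitations

* The duplex predictor requires near-global complementarity; bulged or
  G:U-rich duplexes that a thermodynamic model would accept are missed by
  design (the consensus with the seed predictor is the published
  contract).
* CLASH chimera *discovery* from raw reads is out of scope; chimera
  records are inputs.
* The cascade's conjunctive clauses make the final set order-independent,
  but per-stage rejection attribution does depend on stage order (a
  sequence failing two clauses is reported at the earlier stage).
* Enrichment results depend entirely on the category map supplied; no
  pathway database ships with the package.
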