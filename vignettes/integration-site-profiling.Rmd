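---
title: "Profiling retroviral vector integration sites from simulated LM-PCR libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling retroviral vector integration sites from simulated LM-PCR libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intprofiler)
```

## The problem

Integrating vectors used in haematopoietic gene therapy differ in where
they land. Gammaretroviral (RV, MLV-derived) vectors integrate
preferentially near transcription start sites (TSS), which is the accepted
mechanism behind insertional activation of proto-oncogenes in early
SCID-X1 trials. Foamy-virus (FV) vectors show a much weaker TSS
preference and are therefore considered less genotoxic. The standard desk
assay for this contrast is: recover vector/genome junctions by
ligation-mediated PCR (LM-PCR), map the junction flanks, collapse clones
to independent integration sites, and compare the fraction of sites within
15 kb of a TSS (and near cancer-related genes) between cohorts with a 2x2
chi-square test, together with a TSS-centred integration density profile.

`intprofiler` implements that entire analysis as a tested pipeline. Because
no usable public cohort accompanies the assay, the package includes a
first-class synthetic-data generator: every downstream stage can be
exercised, and its statistical behaviour verified, without any download.

## The generative model

**Genome.** Chromosomes are i.i.d. bases at a fixed GC content (default
0.41, the human average). This is deliberately the *null* sequence model:
every genomic position is exchangeable, so any TSS enrichment measured
downstream is attributable to the integration model, not to sequence
structure.

**Gene model.** `generate_annotation()` places non-overlapping genes
uniformly (lengths uniform in 5--20 kb by default), assigns strands
uniformly, and labels a fraction (default 25%) as `"cancer"`, standing in
for a curated cancer-gene list. The TSS is `tx_start` on `+` genes and
`tx_end - 1` on `-` genes (0-based half-open coordinates throughout). The
optional `min_gap` argument additionally enforces spacing between genes
and from chromosome ends; see *Numerical choices* below.

**Integration.** Sites are drawn from a two-component mixture
(`integration_model()`): with probability `pi_tss` uniformly within
`window_bp` (default 15 kb) of a uniformly chosen TSS, otherwise uniformly
over the genome. Writing `c` for the exact genome fraction covered by the
union of TSS windows (`tss_window_coverage()`), the expected within-window
fraction is

$$\Pr(\text{within } w \text{ of a TSS}) = \pi + (1 - \pi)\,c ,$$

which is the analytic anchor for the calibration and power checks.
`pi_tss` is the single cohort parameter: the shipped Figure-2-style demo
uses 0.08 for the FV-like and 0.28 for the RV-like cohort, values that
reproduce a weak-versus-strong TSS preference of the magnitude reported
for real FV and MLV cohorts once the background term `(1 - pi) c` is
added. Sites colliding at identical positions are redrawn, so a cohort is
a set of distinct, independent loci.

**LM-PCR.** `simulate_lmpcr_reads()` models the junction assay literally:

1. The genomic flank starts at the site position (the base adjacent to the
   LTR end used for amplification) and runs in the site's orientation.
2. The flank is scanned for the first restriction site of the protocol's
   enzymes. MseI (`TTAA`, cut `T^TAA`) defines the fragment end that
   receives the linker; PstI (`CTGCAG`, cut `CTGCA^G`) is co-digested and
   modelled as fragment **loss** whenever its site precedes the first MseI
   site -- its accepted purpose is suppressing internal-vector amplicons.
   The assay itself does not dictate this semantics, so the loss behaviour
   is switchable (`pstI_loss = FALSE`) and every loss is logged with a
   reason code.
3. Recovered fragments must satisfy `min_flank_bp` (default 20) and
   `max_fragment_bp` (default 600, a typical LM-PCR amplicon ceiling).
4. The read is `nested LTR primer + flank + revcomp(nested linker primer)`
   with independent per-base substitution errors (default 0.001, a
   Sanger-scale rate). Only the nested primers appear in reads: in nested
   PCR the inner primer pair defines the final amplicon ends, so the
   first-round primers are carried as protocol metadata only.

The primer and linker sequences shipped as defaults are the literal FV/RV
LTR and MseI-linker reagents of the assay; `lmpcr_protocol("FV")` versus
`lmpcr_protocol("RV")` differ only in the LTR primer pair.

Conservation holds by construction: every input site becomes either reads
or exactly one loss record.

**Recoverability conditioning.** An *observed* cohort of "n independent
integration sites" contains, by construction, only sites whose fragment
survived the digest. `simulate_integrations(..., protocol = )` mirrors
this by redrawing sites whose fragment would be lost. Under the i.i.d.
genome the digest outcome is independent of TSS proximity, so the
conditioning leaves the mixture expectation unchanged; unconditioned
simulation (the default) is appropriate when the loss process itself is
under study.

## Recovery, mapping, collapse

`parse_junction_reads()` is anchored, not floating: the LM-PCR construction
guarantees the LTR primer is a read prefix and the reverse-complemented
linker primer a suffix, each matched within `max_primer_mismatch` (default
1) substitutions. Checks run in a fixed order and the first failure is the
read's status, so statuses partition the library. FASTQ input is accepted;
qualities are read and ignored.

`map_flanks()` is the desk-scale stand-in for BLAT: substitution-only
(no indels), exhaustive over both strands via pigeonhole seed-and-extend
-- with mismatch budget `k` (default 2), a true placement must match one
of `k + 1` disjoint seeds exactly, so exact seed hits enumerate all
candidates, which are then verified by direct mismatch counting. A read is
`mapped` only if its best placement is unique and any runner-up has at
least `uniqueness_margin` (default 2) more mismatches; otherwise
`ambiguous` or `unmapped`. The reported position is the first flank base
in junction orientation, i.e. exactly the simulator's site coordinate, so
error-free libraries round-trip to bit-identical site sets. The
substitution-only restriction keeps the mapper provably equivalent to an
exhaustive scan (the test suite checks this equivalence on every status
against an independent full-scan oracle) at the cost of missing indel-ed
flanks -- a documented divergence from BLAT, which tolerates gaps.

`collapse_to_independent_sites()` merges reads within `merge_bp` on the
same chromosome and orientation (single-linkage; representative = smallest
position). The assay literature rarely states its deduplication criterion;
the default of 3 bp absorbs junction-trimming slippage from sequencing
errors, while `merge_bp = 0` gives exact deduplication and is what the
error-free round-trip checks use.

## Annotation and statistics

`classify_sites()` reports, per site: inside a transcriptional unit
(`tx_start <= pos < tx_end`); signed distance to the nearest TSS (positive
= downstream in the gene's orientation, ties broken by smaller gene id);
within 15 kb of a TSS; and within 30 kb of each labelled gene set. Two
conventions are deliberate and exposed:

* the 15-kb TSS window is **symmetric and boundary-inclusive** -- the assay
  counts sites "immediately up or downstream" of the TSS without further
  qualification, and a symmetric window is the assumption-free reading;
* "within 30 kb of a labelled gene" measures distance to the **gene
  interval** (0 inside, so inside-gene hits count -- cohort reports in
  this assay count a site inside a cancer gene in this category), with
  `label_anchor = "tss"` available as the alternative reading.

`tss_density_profile()` bins the signed nearest-TSS distance over a 100-kb
window and reports percent of all integrations per kb, so unequal bin
widths remain comparable. Default edges sit at 0, ±1, ±5, ±10, ±25 and ±50
kb -- geometric-style spacing that resolves the sharp enrichment near the
TSS while keeping outer bins well-populated; any strictly increasing edge
vector spanning the window is accepted. Mass is conserved exactly:
`sum(percent_per_kb * width_kb) = 100 * (in-window fraction)`.

`compare_categories()` builds the 2x2 table and computes the Pearson
chi-square statistic from the closed form
$n(ad - bc)^2 / (r_1 r_2 c_1 c_2)$ with 1 df, the Yates-corrected variant,
or the exact two-sided Fisher p. Pearson without continuity correction is
the default: on the published 13/100-vs-25/100 table both variants are
significant (p = 0.031 and 0.047), and the uncorrected statistic is the
conventional choice at these counts. The expected-cell advisory threshold
is 1 (not 5) because Fisher is always available and the advisory is not a
gate -- the computation is still returned. No multiple-testing correction
is applied: the assay makes a small number of pre-specified comparisons.

```{r chisq}
compare_categories(13, 100, 25, 100, method = "pearson")
```

## The orchestrated run

`run_pipeline()` executes simulate (or load) -> parse -> map -> collapse
-> classify -> profile -> compare from a single declarative config (R list
or YAML), logs per-stage counts so conservation can be audited
(`sites = reads + losses`, `reads = ok + rejected`,
`ok = mapped + unmapped + ambiguous`), embeds the resolved config in the
report for provenance, and is deterministic: identical configs give
byte-identical outputs. `figure2_demo_config()` ships the two-cohort
demo; `inst/scripts/intprofiler.R` exposes the stages as shell
subcommands.

```{r demo, eval = FALSE}
report <- run_pipeline(figure2_demo_config(seed = 42))
report
```

## Numerical choices and degenerate inputs

* **Coordinates** are 0-based half-open everywhere; BED export is
  therefore direct. The junction base (first genomic base after the LTR)
  defines a site in simulator, mapper and annotator alike, which is what
  makes round-trip equality exact rather than off-by-one.
* **Ties.** Nearest-TSS ties break to the lexicographically smaller gene
  id; equal-scoring mapper placements are ambiguous, never arbitrarily
  resolved.
* **Degenerate tables** (a zero margin) return statistic 0, p = 1: no
  association is testable.
* **Sites on gene-less chromosomes** have undefined TSS distance; they are
  excluded from profiles (reported as `n_unassigned`) and never counted as
  within-window.
* **Flat-profile geometry.** The uniform background is flat in
  nearest-TSS distance only where TSS windows neither overlap one another
  nor clip chromosome ends; `min_gap = 100` kb in `generate_annotation()`
  enforces exactly that, and the flatness checks use it. With overlapping
  windows, nearest-assignment shifts mass inward -- a property of the
  statistic, not a bug.
* **Problem sizes.** The shipped studies use 1--3 Mb chromosomes, 8--12
  genes, cohorts of 100 (demo; the scale of a subcloned Sanger library)
  to 1,000 (calibration), 10,000 sites for profile calibration, and 200
  replicates for power -- sizes at which every binomial/Poisson band used
  in the checks is already narrow relative to the effects being measured.

## What the synthetic data does and does not show

The generator emulates the *statistical* structure the analysis assumes:
a mixture-shaped TSS preference against a uniform background, literal
digest/primer chemistry, substitutional read errors and clone collapse.
It does not emulate chromatin or sequence-motif integration bias,
CpG/isochore structure, repeat-driven multi-mapping at human-genome scale,
PCR duplicate families (a `duplicates` multiplier exists but default
libraries emit one read per recovered site), indels, or quality-score
structure. Passing tests therefore certify the pipeline's correctness and
calibration under its stated model -- they do not certify that a real
cohort's enrichment will match the mixture, and the mapper's
substitution-only model means heavily indel-ed real reads would go
unmapped rather than mismapped.

## Known limitations

Exhaustive-equivalent mapping is quadratic-ish in genome size times read
count and intended for desk-scale genomes (tens of Mb at most), not a
full human genome; the microRNA-gene category of the published assay is
representable only as a user-supplied label set; and the chi-square
comparison addresses one category at a time, as the assay does, rather
than modelling the joint site-annotation distribution.
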