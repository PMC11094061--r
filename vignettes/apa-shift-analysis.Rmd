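---
title: "Quantifying 3'UTR shortening from coverage: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3'UTR shortening from coverage: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apashift)
```

# The problem

When T cells are activated — or more generally when cells switch
proliferative state — many transcripts change which of their competing
3'UTR cleavage/polyadenylation sites (PAS) they use. Increased use of the
proximal PAS shortens the 3'UTR, removing regulatory elements that control
stability, translation and localization of the message. apashift
quantifies this from per-base 3'UTR read coverage, calls events between
conditions, and layers on the classifications a T-cell activation study
design needs: time point (8 h vs 48 h), CD28 costimulation dependence,
PAS signal strength, and positional maps of the RBM3 binding motif, whose
AAUAUA hexamer resembles the core PAS signal AAUAAA and which is proposed
to competitively block distal PAS usage early after activation.

# The two-segment coverage model

A gene expressing a mixture of a short isoform (ending at the proximal
breakpoint `b`) and a long isoform (ending at the annotated distal UTR
end) has expected per-base depth

$$ d_s(x) = w_{L,s} + w_{S,s}\,\mathbf{1}(x < b), \qquad
   w_{L,s}, w_{S,s} \ge 0 . $$

`fit_two_segment()` searches `b` exhaustively over
`[search_min, L - search_min]`. For a fixed `b`, the non-negative
least-squares solution is closed form: with upstream and downstream
segment means $m_1, m_2$, the fit is $w_L = m_2$, $w_S = m_1 - m_2$ when
$m_1 \ge m_2$; otherwise the short-isoform weight is clamped to zero and
the free parameter refit as the overall mean (coverage rising toward the
3' end is not interpretable as isoform mixing in this model). The
breakpoint is fitted *jointly*: residual sums of squares are summed over
every sample of every condition, reflecting a single shared proximal PAS
per gene. The per-sample usage statistic is
$\mathrm{PDUI} = 100\,w_L/(w_L + w_S)$.

Numerical choices:

* **Ties** in the joint residual are broken toward the most distal
  candidate. This is deterministic and biases *against* calling spurious
  shortening.
* **Flat-fit guard**: if the best two-segment fit does not reduce the
  one-segment (flat) residual by at least `min_fit_gain` (default 5%
  fractionally), the gene is reported as single-isoform
  (`qc_flag = "no_breakpoint"`, PDUI 100, no breakpoint). A perfectly flat
  noiseless gene falls in this branch, which is exactly the PDUI-100
  definitional limit.
* **Guards**: `search_min` (default 100 nt) keeps degenerate edge
  breakpoints out of the search; `min_mean_depth` (default 1 RPM) flags
  unassessable genes as `low_coverage` instead of fitting them.
* Scale invariance holds by construction: rescaling all tracks of a gene
  rescales both weights and leaves breakpoint and PDUI unchanged.

# Testing events

`test_event()` reports `dPDUI = mean(PDUI_stim) − mean(PDUI_ref)` and a
raw p-value. The default test is Fisher's exact test on the 2×2 table of
pooled, rounded long/short abundances per group: with three replicates
(donors) per condition a replicate-level location test has almost no
power, while the exact test on pooled abundances behaves sensibly and is
oracle-testable by full enumeration. A Welch t-test on per-replicate PDUI
is exposed as `method = "t"` so the choice is auditable. Because the
pooled abundances are RPM-scale quantities rather than raw read counts,
the exact test is conservative at typical depths — acceptable for an
analysis whose calling rule also demands `|dPDUI| > 20`.

`adjust_and_call()` applies Benjamini–Hochberg across the comparison
batch and the threshold rules: shortened/lengthened at
`|dPDUI| ≥ 20` with adjusted p < 0.05; non-changing at `|dPDUI| < 3` with
raw p > 0.05; everything else indeterminate. The indeterminate band is
deliberate: an event with, say, a 15-point shift is neither evidence of
change nor evidence of stability, and the temporal classifier
(`temporal_classify()`) therefore treats only an explicit non-changing
call at the other time point as license for an "8 h-only" / "48 h-only"
label; indeterminate combinations fall into `other`.

Other classification layers and their parameters:

* `basal_pdui_bin()`: basal-state bins at 33/66. Only the "long > 66" cut
  is externally meaningful; the 33 cut completes it symmetrically into
  tertiles.
* `cd28_ratio()`: `|dPDUI_CD3/CD28| / max(|dPDUI_CD3|, 1)`, enhanced when
  > 2. The 1-point floor prevents near-zero denominators from skewing the
  ratio. Sign-discordant pairs are flagged and excluded from the enhanced
  fraction rather than silently folded in, because the ratio is only
  meaningful for co-directional changes.
* `condition_correlation()`: Pearson r plus OLS slope/intercept on paired
  dPDUI vectors. The correlation set defaults, in the pipeline, to events
  significant under the costimulated condition; both union and
  intersection restrictions can be built from the comparison table.

# Motif analyses

`pas_signal_presence()` searches for the core PAS hexamer AAUAAA and the
CFI element UGUA entirely within the 100 nt strictly upstream of a
cleavage position (transcript orientation). `motif_positional_map()`
slides a 10-nt window at 1-nt steps across offsets (default −100..+100;
offset 0 = cleavage position) and reports, per offset, the *fraction of
events* whose window contains at least one exact occurrence of the target
motif — presence/absence per event, not match counts. Occurrences whose
own 6-mer equals the excluded hexamer (AAUAAA) are never counted; for the
literal AAUAUA target this is a no-op, but it generalizes to degenerate
user-supplied patterns. Smoothing is a centered 5-offset running mean
with shrinking windows at the span edges (no span truncation). Matching
is exact substring matching throughout — the motifs of interest are
literal hexamers, so no IUPAC degeneracy or PWM machinery is warranted.
Proximal sites come from the fitted breakpoints by default; a
user-supplied override table (e.g. sites validated by an independent
algorithm) replaces them per gene, which is also how the PAS-strength
analysis can be restricted to a cross-validated event set
(`pas_strength_summary(event_filter = ...)`).

# Enrichment

`overlap_enrichment()` is the standard hypergeometric upper tail
(equivalently one-sided Fisher), with fold enrichment
`(overlap/query)/(set/background)` and the conventional
p < 0.05 & fold > 2 pass filter. The background in the pipeline is the
set of *assessable* genes (those with a usable PDUI fit), not all genes:
enrichment among APA-measurable genes is the relevant null, and a
whole-transcriptome background would inflate it. Annotation content
(e.g. GO, RBP target lists) is supplied by the user as plain gene lists;
no database is bundled.

# The synthetic-data generator

`generate_truth()` + `write_annotation_and_sequence()` +
`simulate_coverage()` emulate the statistical structure the analysis
assumes, with full knowledge of ground truth:

* **Design**: five condition labels (naive; CD3 and CD3/CD28 at 8 h and
  48 h) with three replicates each, mirroring a three-donor stimulation
  time course. Labels carry semantics: the first is the reference, "48"
  marks late, "CD28" marks costimulation.
* **Effects**: a configurable majority of genes shorten
  (`frac_shortened`, default 0.6 vs 0.1 lengthened), with basal PDUI of
  to-be-shortened genes drawn Uniform(66, 100) — APA genes predominantly
  start long — lengthened genes Uniform(0, 34), unchanged genes
  Uniform(20, 80). True |dPDUI| is drawn from `dpdui_range`
  (default 25–60, clearing the 20-point calling threshold). `frac_early`
  (default 0.35) of changing genes shift already at 8 h, echoing the
  roughly 1:2 ratio of early to late event counts in activation time
  courses; the rest shift only at 48 h.
* **Noise**: replicate-level PDUI jitter is Normal (default SD 5
  percentage points, a free parameter — donor-level PDUI variance is not
  an externally fixed quantity) truncated to [0, 100] by clipping;
  positional noise is Poisson by default, negative binomial
  (`size = 1/dispersion`) when overdispersion is wanted, or none for
  noiseless definitional checks.
* **Sequence**: uniform A/C/G/T background. The canonical AATAAA is
  planted wholly within 100 nt upstream of the proximal / distal site
  with probability `pas_fidelity_p` / `pas_fidelity_d` (defaults 0.4 and
  0.9: proximal signals are characteristically weaker). Non-planted sites
  receive a scrambled permutation instead, and their upstream regions are
  scrubbed of chance AATAAA occurrences so that rescanning the FASTA
  recovers the planted incidence exactly. RBM3-regulated genes (a
  `frac_rbm3` subset of the early-shortened genes) get an AATATA planted
  within ±25 nt of the distal site.
* **Library size**: the manifest's `total_mapped_reads` is the
  configurable `library_size` (default 1e6), not the within-slice
  coverage sum — the simulated UTRs are a small slice of a transcriptome,
  and the default makes RPM-normalized depth numerically equal to raw
  simulated depth, keeping `mean_depth` interpretable after
  normalization.
* **Coordinates and strand**: 0-based half-open throughout; BED6 and
  bedGraph in genomic orientation; minus-strand genes are simulated in
  transcript orientation and reversed on write, so "upstream" always
  means 5' on the transcript. Identical configurations (including seed)
  produce byte-identical files.

What the generator does *not* emulate: read-level artifacts (fragment
length, mappability, internal priming), multi-breakpoint (>2 isoform)
genes, intronic PAS, between-gene coverage correlation, and
condition-dependent expression changes. Passing tests on synthetic data
therefore demonstrate correctness of the estimator and calling logic
under the stated model, not robustness to alignment artifacts in real
libraries.

# Validation strategy and problem sizes

The test suite validates each layer against an independent oracle: the
breakpoint fit against an exhaustive brute-force minimizer on 50 genes of
400–800 nt; the exact tests against full hypergeometric enumeration; BH
against the hand-written step-up procedure; the motif map against a naive
per-offset rescan. Statistical recovery runs use 200 genes at mean depth
30 with Poisson noise and 3-point replicate PDUI jitter (PDUI RMSE below
5 points, median breakpoint error within 20 nt), 500 genes for
CD28-enhancement recovery (30% of genes planted at 2.5× dPDUI; the
planted |dPDUI| range 25–30 keeps the 2.5-fold enhanced shifts on the
PDUI scale without clipping at 0, so the planted ratio is exactly 2.5),
260 genes for RBM3 planted-signal recovery, and 1000 genes for type-I
control of the event test with no planted effect. These sizes give the
recovery statistics stable sampling distributions while keeping the whole
suite inside a few minutes on one CPU.

# Known limitations

* The breakpoint model assumes exactly one proximal site per gene; genes
  with three or more expressed isoforms are fit to the dominant step.
* The Fisher test treats pooled RPM abundances as counts; its p-values
  are calibrated conservatively rather than exactly, and the Welch
  alternative is underpowered at n = 3. Neither is a substitute for a
  replicate-aware count model when many replicates are available.
* The motif layer consumes per-gene transcript-oriented FASTA records (as
  the simulator writes); slicing windows from a genome-level FASTA is not
  implemented.
* Breakpoints are fitted jointly across all conditions; a gene whose
  proximal site itself switches between conditions would be averaged.
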