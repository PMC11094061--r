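# apashift

Alternative polyadenylation (APA) shift analysis from per-base 3'UTR read
coverage, for transcriptomics analysts studying condition-dependent 3'UTR
shortening and lengthening — the motivating system being primary human CD4+
T cells stimulated through CD3 with or without CD28 costimulation at 8 h
and 48 h.

## The model

Most genes carry two competing cleavage/polyadenylation sites in their
3'UTR: a proximal PAS (pPAS, short isoform) and a distal PAS (dPAS, long
isoform). Read coverage over the UTR is modelled as a two-segment step:

```
depth_s(x) ≈ w_L,s + w_S,s · 1(x < b),     w_L, w_S ≥ 0
```

where `b` is the (shared, de novo) proximal breakpoint, `w_L` the
long-isoform abundance (covers the whole UTR) and `w_S` the short-isoform
abundance (covers only positions upstream of `b`) for sample `s`. The
breakpoint is chosen by exhaustive search, minimizing the residual sum of
squares jointly over all samples of a gene; the per-sample usage statistic
is the PDUI (Percentage of Distal polyA site Usage Index):

```
PDUI = 100 · w_L / (w_L + w_S)        # 100 = long UTR only, 0 = short only
```

Between two conditions, `dPDUI = mean(PDUI_stim) − mean(PDUI_ref)`.
Events with `|dPDUI| > 20` and Benjamini–Hochberg adjusted p < 0.05
(Fisher's exact test on pooled long/short abundances) are called shortened
or lengthened; events with `|dPDUI| < 3` and raw p > 0.05 are
non-changing. Downstream layers classify events by time point
(8 h-only / 48 h-only / both), CD28 enhancement (|dPDUI| ratio > 2 with a
1-point denominator floor), PAS signal strength (AAUAAA / UGUA within
100 nt upstream of each site), RBM3-motif (AAUAUA) positional density
around sites (10-nt sliding window, 5-offset running mean), and gene-set
overrepresentation (hypergeometric upper tail).

A seeded synthetic-data generator emits BED/FASTA/bedGraph inputs with
known ground truth (true PDUI per condition, planted PAS hexamers with
configurable fidelity, planted RBM3 motifs near distal sites), so every
stage is testable end to end without external data.

## Worked example

```r
library(apashift)
cfg <- apa_run_config(
  sim = sim_config(n_genes = 60, frac_shortened = 0.6, frac_lengthened = 0.1,
                   frac_early = 0.5, frac_rbm3 = 1, replicate_pdui_sd = 3,
                   seed = 42))
res <- run_apa_pipeline(cfg, "demo_run")
print(res$summary, row.names = FALSE)
```

```
                 metric  comparison      value
    direction_shortened      CD3_8h 18.0000000
   direction_lengthened      CD3_8h  3.0000000
    direction_shortened     CD3_48h 36.0000000
   direction_lengthened     CD3_48h  6.0000000
        basal_bin_short         all 10.0000000
          basal_bin_mid         all 11.0000000
         basal_bin_long         all 39.0000000
      temporal_48h_only         CD3 16.0000000
          temporal_both         CD3 21.0000000
         temporal_other         CD3 23.0000000
 cd28_enhanced_fraction          8h  0.0000000
              pearson_r          8h  0.9969229
       regression_slope          8h  0.9848642
```

(abridged; the run also writes per-stage TSVs under `demo_run/`). Reading
the output: of the 60 simulated genes, half of the planted shorteners
shift already at 8 h (18 called shortened) and all of them by 48 h (36),
against 3 and 6 lengthened — the planted 6:1 direction bias. Most
APA genes start from long basal UTRs (39 of 60 with basal PDUI > 66).
No CD28 enhancement was planted, so the enhanced fraction is 0 and the
CD3 vs CD3/CD28 dPDUI correlation is ≈ 1 with slope ≈ 1. The enrichment
stage recovers the planted RBM3-regulated set among 8 h-shortened genes
(fold enrichment 3.3, hypergeometric p ≈ 1e−15):

```r
res$enrichment[, c("query", "set", "overlap_n", "fold_enrichment", "p_value")]
#>                  query        set overlap_n fold_enrichment  p_value
#>       shortened_CD3_8h rbm3_truth        18            3.33 1.08e-15
#>      shortened_CD3_48h rbm3_truth        18            1.67 9.81e-06
```

A thin CLI wrapper is in `inst/scripts/apashift.R`:

```sh
Rscript inst/scripts/apashift.R --config run.yaml --outdir runs/demo --seed 7
```

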