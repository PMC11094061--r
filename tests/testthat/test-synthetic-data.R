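test_that("sim_config rejects inconsistent fractions and geometry", {
  expect_error(sim_config(frac_shortened = 0.8, frac_lengthened = 0.3),
               "frac_shortened")
  expect_error(sim_config(min_pas_separation = 700,
                          utr_length_range = c(600, 900)),
               "min_pas_separation")
  expect_error(sim_config(pas_fidelity_p = 1.4), "pas_fidelity_p")
  expect_error(sim_config(dpdui_range = c(10, 30)), "dpdui_range")
  expect_silent(sim_config(n_genes = 5))
})

test_that("truth generator plants the configured effect structure", {
  # no planted effect: PDUI identical across conditions
  cfg0 <- sim_config(n_genes = 20, frac_shortened = 0, frac_lengthened = 0,
                     seed = 7)
  tr0 <- generate_truth(cfg0)
  pd <- matrix(tr0$pdui$true_pdui, nrow = 20)
  expect_true(all(apply(pd, 1, function(x) diff(range(x)) == 0)))

  # exactly 60/100 genes shortened by more than 20 points at 48 h
  cfg <- sim_config(n_genes = 100, frac_shortened = 0.6,
                    frac_lengthened = 0.1, seed = 1)
  tr <- generate_truth(cfg)
  naive <- tr$pdui$true_pdui[tr$pdui$condition == "naive"]
  stim <- tr$pdui$true_pdui[tr$pdui$condition == "CD3_48h"]
  expect_identical(sum(stim < naive - 20), 60L)
  expect_identical(sum(tr$genes$status == "shortened"), 60L)
  expect_identical(sum(tr$genes$status == "lengthened"), 10L)

  # basal regimes: to-be-shortened genes start from long 3'UTRs
  expect_true(all(naive[tr$genes$status == "shortened"] > 66))
  expect_true(all(tr$genes$proximal_offset > 0 &
                    tr$genes$proximal_offset < tr$genes$utr_length))
  expect_true(all(tr$genes$expression > 0))
  expect_true(all(tr$pdui$true_pdui >= 0 & tr$pdui$true_pdui <= 100))

  # determinism
  expect_identical(generate_truth(cfg), tr)
})

test_that("CD28 enhancement multiplies the planted shift under costimulation", {
  cfg <- sim_config(n_genes = 50, frac_shortened = 1, frac_lengthened = 0,
                    frac_early = 1,
                    frac_cd28_enhanced = 0.4, dpdui_range = c(25, 30),
                    seed = 11)
  tr <- generate_truth(cfg)
  wide <- reshape(tr$pdui, idvar = "gene_id", timevar = "condition",
                  direction = "wide")
  naive <- wide$true_pdui.naive
  d3 <- wide$true_pdui.CD3_8h - naive
  d28 <- wide$true_pdui.CD3CD28_8h - naive
  enh <- tr$genes$cd28_enhanced[match(wide$gene_id, tr$genes$gene_id)]
  expect_identical(sum(enh), 20L)
  # non-enhanced genes shift identically under both stimuli
  expect_equal(d28[!enh], d3[!enh])
  # enhanced genes shift 2.5x (up to clamping at PDUI 0)
  unclamped <- enh & wide$true_pdui.CD3CD28_8h > 0
  expect_equal(d28[unclamped], 2.5 * d3[unclamped])
})

test_that("sequence writer honors the motif planting contracts", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 40, pas_fidelity_p = 1, pas_fidelity_d = 1,
                    frac_shortened = 1, frac_lengthened = 0, frac_early = 1,
                    frac_rbm3 = 1, seed = 13)
  tr <- generate_truth(cfg)
  ann <- write_annotation_and_sequence(tr, dir)
  seqs <- as.character(Biostrings::readDNAStringSet(ann$fasta))

  # independent string rescan: AATAAA fully within 100 nt upstream of both
  # sites for every gene at fidelity 1
  for (i in seq_len(nrow(tr$genes))) {
    s <- seqs[[tr$genes$gene_id[i]]]
    p <- tr$genes$proximal_offset[i]
    L <- tr$genes$utr_length[i]
    expect_true(grepl("AATAAA", substr(s, p - 100 + 1, p), fixed = TRUE))
    expect_true(grepl("AATAAA", substr(s, L - 100 + 1, L), fixed = TRUE))
    # every rbm3-regulated gene carries AATATA within 25 nt of the dPAS
    expect_true(grepl("AATATA", substr(s, L - 25 + 1, L + 25), fixed = TRUE))
  }
  expect_true(all(nchar(seqs) == tr$genes$utr_length + cfg$seq_flank))

  # fidelity 0: rescanning finds no canonical signal at any site
  cfg0 <- sim_config(n_genes = 40, pas_fidelity_p = 0, pas_fidelity_d = 0,
                     seed = 13)
  tr0 <- generate_truth(cfg0)
  ann0 <- write_annotation_and_sequence(tr0, file.path(dir, "f0"))
  seqs0 <- as.character(ann0$sequences)
  for (i in seq_len(nrow(tr0$genes))) {
    s <- seqs0[[tr0$genes$gene_id[i]]]
    p <- tr0$genes$proximal_offset[i]
    L <- tr0$genes$utr_length[i]
    expect_false(grepl("AATAAA", substr(s, p - 100 + 1, p), fixed = TRUE))
    expect_false(grepl("AATAAA", substr(s, L - 100 + 1, L), fixed = TRUE))
  }
})

test_that("planted proximal-PAS fidelity is recovered by independent rescan", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 400, pas_fidelity_p = 0.4, pas_fidelity_d = 0.9,
                    seed = 17)
  tr <- generate_truth(cfg)
  ann <- write_annotation_and_sequence(tr, dir)
  seqs <- as.character(ann$sequences)
  has_p <- mapply(function(gid, p)
    grepl("AATAAA", substr(seqs[[gid]], p - 100 + 1, p), fixed = TRUE),
    tr$genes$gene_id, tr$genes$proximal_offset)
  # 0.4 planted + ~2.3% background occurrence, n = 400
  expect_gt(mean(has_p), 0.33)
  expect_lt(mean(has_p), 0.50)
})

test_that("simulated coverage realizes the two-isoform model", {
  cfg <- sim_config(n_genes = 1, utr_length_range = c(1000, 1000),
                    noise_model = "none", replicate_pdui_sd = 0,
                    conditions = "naive", n_replicates = 1, seed = 5)
  # PDUI 0: constant before the proximal site, zero after
  cov0 <- simulate_coverage(apa_truth(cfg, 1000, 400, 0))
  d0 <- cov0$depth[[1]][, 1]
  expect_true(all(d0[1:400] == d0[1]) && d0[1] > 0)
  expect_true(all(d0[401:1000] == 0))
  # PDUI 100: flat across the entire UTR
  d100 <- simulate_coverage(apa_truth(cfg, 1000, 400, 100))$depth[[1]][, 1]
  expect_true(all(d100 == d100[1]) && d100[1] > 0)
  # conservation: downstream/upstream mean ratio equals true PDUI / 100
  for (p in c(12.5, 40, 85)) {
    d <- simulate_coverage(apa_truth(cfg, 1000, 400, p))$depth[[1]][, 1]
    expect_equal(mean(d[401:1000]) / mean(d[1:400]), p / 100,
                 tolerance = 1e-9)
  }
})

test_that("identical seeds give byte-identical files, different seeds differ", {
  cfg <- sim_config(n_genes = 6, seed = 23, utr_length_range = c(400, 700),
                    conditions = c("naive", "CD3_8h"), n_replicates = 2)
  md5_run <- function(cfg) {
    dir <- withr::local_tempdir()
    tr <- generate_truth(cfg)
    write_annotation_and_sequence(tr, dir)
    simulate_coverage(tr, outdir = dir)
    write_truth_table(tr, file.path(dir, "truth.tsv"))
    files <- setdiff(list.files(dir, full.names = TRUE),
                     file.path(dir, "samples.tsv"))  # holds absolute paths
    out <- unname(tools::md5sum(sort(files)))
    names(out) <- basename(sort(files))
    out
  }
  expect_identical(md5_run(cfg), md5_run(cfg))
  cfg2 <- sim_config(n_genes = 6, seed = 24, utr_length_range = c(400, 700),
                     conditions = c("naive", "CD3_8h"), n_replicates = 2)
  expect_false(identical(md5_run(cfg), md5_run(cfg2)))
})

test_that("negative binomial noise is overdispersed relative to Poisson", {
  cfg <- sim_config(n_genes = 1, utr_length_range = c(2000, 2000),
                    conditions = "naive", n_replicates = 1,
                    noise_model = "negative_binomial", nb_dispersion = 0.5,
                    replicate_pdui_sd = 0, mean_depth = 50, seed = 2)
  d <- simulate_coverage(apa_truth(cfg, 2000, 1000, 100))$depth[[1]][, 1]
  expect_true(all(d >= 0))
  # var = mu + dispersion * mu^2 >> mu at dispersion 0.5, mu 50
  expect_gt(var(d), 2 * mean(d))
})
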