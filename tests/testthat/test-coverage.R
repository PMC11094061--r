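write_bed <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_utr_bed parses strand-aware annotations", {
  f <- write_bed(c("chr1\t100\t600\tgeneA\t0\t+",
                   "chr1\t700\t1000\tgeneB\t0\t-"))
  anno <- read_utr_bed(f)
  expect_equal(anno$start, c(100, 700))
  expect_equal(anno$end, c(600, 1000))
  expect_equal(anno$utr_length, c(500, 300))
  # distal site: end on plus strand, start on minus
  expect_equal(anno$distal_site, c(600, 700))
})

test_that("read_utr_bed rejects duplicated gene ids", {
  f <- write_bed(c("chr1\t100\t600\tgeneA\t0\t+",
                   "chr1\t700\t1000\tgeneA\t0\t-"))
  expect_error(read_utr_bed(f), "duplicated gene_id.*geneA")
})

test_that("load_coverage expands intervals to dense per-base vectors", {
  bed <- write_bed("chr1\t100\t600\tgeneA\t0\t+")
  anno <- read_utr_bed(bed)

  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t100\t600\t5", bg)
  tr <- load_coverage(bg, anno)
  expect_equal(tr$geneA$depth, rep(5, 500))

  # abutting intervals become a step; oracle by direct per-base expansion
  writeLines(c("chr1\t100\t300\t2", "chr1\t300\t600\t4"), bg)
  tr <- load_coverage(bg, anno)
  expect_equal(tr$geneA$depth, c(rep(2, 200), rep(4, 300)))

  # positions absent from the bedGraph are zero
  writeLines("chr1\t150\t160\t3", bg)
  tr <- load_coverage(bg, anno)
  oracle <- numeric(500); oracle[51:60] <- 3
  expect_equal(tr$geneA$depth, oracle)

  # empty bedGraph: all-zero vectors
  writeLines(character(0), bg)
  expect_equal(load_coverage(bg, anno)$geneA$depth, numeric(500))

  # negative values rejected
  writeLines("chr1\t100\t110\t-1", bg)
  expect_error(load_coverage(bg, anno), "negative")
})

test_that("minus-strand tracks are flipped into transcript orientation", {
  bed <- write_bed("chr1\t100\t600\tgeneM\t0\t-")
  anno <- read_utr_bed(bed)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t100\t101\t7", bg)  # genomic start base = transcript 3' end
  tr <- load_coverage(bg, anno)
  expect_equal(tr$geneM$depth[500], 7)
  expect_equal(sum(tr$geneM$depth), 7)
  writeLines("chr1\t599\t600\t9", bg)  # genomic end base = transcript 5' base
  expect_equal(load_coverage(bg, anno)$geneM$depth[1], 9)
})

test_that("normalize_rpm scales linearly and guards its preconditions", {
  tr <- coverage_track("g", c(2, 4))
  expect_equal(normalize_rpm(tr, 2e6)$depth, c(1, 2))
  expect_equal(normalize_rpm(tr, 1e6)$depth, c(2, 4))  # identity at 1M reads

  set.seed(1)
  d <- runif(50, 0, 100)
  tot <- 3.7e6
  expect_equal(normalize_rpm(coverage_track("g", d), tot)$depth,
               d * 1e6 / tot)  # element-wise oracle

  expect_error(normalize_rpm(tr, 0), "positive")
  expect_error(normalize_rpm(normalize_rpm(tr, 1e6), 1e6),
               "already normalized")
})

test_that("average_replicates takes position-wise means with validation", {
  mk <- function(d, gene = "g", cond = "naive") {
    t <- coverage_track(gene, d, condition = cond)
    normalize_rpm(t, 1e6)
  }
  t1 <- mk(c(0, 2)); t2 <- mk(c(4, 0))
  avg <- average_replicates(list(t1, t2))
  expect_equal(avg$depth, c(2, 1))
  expect_true(is.na(avg$replicate))
  expect_equal(avg$condition, "naive")

  # idempotence on identical tracks
  expect_equal(average_replicates(list(t1, t1, t1))$depth, t1$depth)

  # random tracks vs direct position-wise mean
  set.seed(2)
  ts <- replicate(3, mk(runif(30)), simplify = FALSE)
  expect_equal(average_replicates(ts)$depth,
               rowMeans(sapply(ts, `[[`, "depth")))

  expect_error(average_replicates(list(t1, mk(c(1, 2), gene = "h"))),
               "different genes")
  expect_error(average_replicates(list(t1, mk(c(1, 2, 3)))),
               "unequal lengths")
  expect_error(average_replicates(list(coverage_track("g", c(1, 2)))),
               "normalized")
})

test_that("simulator output round-trips through the readers exactly", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 6, seed = 31, utr_length_range = c(400, 700),
                    conditions = c("naive", "CD3_8h"), n_replicates = 2)
  tr <- generate_truth(cfg)
  ann <- write_annotation_and_sequence(tr, dir)
  cov_mem <- simulate_coverage(tr, outdir = dir)

  anno <- read_utr_bed(ann$bed)
  expect_equal(anno$gene_id, tr$genes$gene_id)
  expect_equal(anno$start, tr$genes$start)
  expect_equal(anno$end, tr$genes$end)
  expect_equal(anno$strand, tr$genes$strand)

  # file-based coverage equals the in-memory tracks after undoing RPM
  cov_file <- load_coverage_set(file.path(dir, "samples.tsv"), anno)
  fac <- 1e6 / cfg$library_size
  for (gid in names(cov_mem$depth)) {
    expect_equal(cov_file$depth[[gid]], cov_mem$depth[[gid]] * fac,
                 tolerance = 1e-12)
  }
})

test_that("condition-averaged bedGraph matches replicate means", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 3, seed = 37, utr_length_range = c(400, 500),
                    conditions = c("naive", "CD3_8h"), n_replicates = 3)
  tr <- generate_truth(cfg)
  write_annotation_and_sequence(tr, dir)
  simulate_coverage(tr, outdir = dir)
  anno <- read_utr_bed(file.path(dir, "utr.bed"))
  cov <- load_coverage_set(file.path(dir, "samples.tsv"), anno)
  out <- file.path(dir, "naive_mean.bedGraph")
  write_condition_bedgraph(cov, "naive", out)
  back <- load_coverage(out, anno, condition = "naive", replicate = 1L)
  idx <- which(cov$samples$condition == "naive")
  for (gid in anno$gene_id) {
    expect_equal(back[[gid]]$depth,
                 rowMeans(cov$depth[[gid]][, idx]), tolerance = 1e-6)
  }
})
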