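# Synthetic-data generator: two-isoform 3'UTR coverage with known ground
# truth, PAS hexamer planting, and RBM3-motif planting near distal sites.

#' Configuration for the synthetic APA data generator
#'
#' Bundles every knob of the simulator into a validated object. The defaults
#' emulate the structure of a T-cell activation time course: a naive
#' reference plus CD3 / CD3+CD28 stimulation at 8 h and 48 h, three
#' replicates (donors) per condition, and a majority-shortening APA regime.
#'
#' Condition labels carry their own semantics: the first label is the
#' unstimulated reference; a label containing `"48"` is a late time point
#' (otherwise early); a label containing `"CD28"` receives the planted CD28
#' enhancement (if any).
#'
#' @param n_genes number of simulated genes.
#' @param utr_length_range integer pair, min/max 3'UTR length in nt.
#' @param min_pas_separation minimum distance (nt) between the proximal
#'   breakpoint and the distal UTR end.
#' @param conditions character vector of condition labels; the first is the
#'   unstimulated reference.
#' @param n_replicates replicates per condition.
#' @param mean_depth expected raw read depth per base for a gene with
#'   expression multiplier 1 when only the long isoform is expressed.
#' @param noise_model positional count noise: `"poisson"`,
#'   `"negative_binomial"` or `"none"`.
#' @param nb_dispersion dispersion of the negative binomial noise
#'   (`size = 1/nb_dispersion`); ignored otherwise.
#' @param replicate_pdui_sd SD (percentage points) of the replicate-level
#'   PDUI around its condition truth, truncated to \[0, 100\].
#' @param frac_shortened,frac_lengthened proportion of genes whose 3'UTR
#'   shortens / lengthens upon stimulation; the remainder are unchanged.
#' @param frac_early proportion of the changing genes whose shift is already
#'   present at the early time point (the rest shift only at 48 h).
#' @param frac_rbm3 proportion of early-shortened genes that carry a planted
#'   AAUAUA motif near the distal PAS ("RBM3-regulated" genes).
#' @param frac_cd28_enhanced proportion of shortened genes whose true dPDUI
#'   is multiplied by `cd28_enhance_factor` under CD28-costimulated
#'   conditions.
#' @param cd28_enhance_factor multiplier for the CD28-enhanced subset.
#' @param dpdui_range range (percentage points) of the true |dPDUI| drawn for
#'   changing genes.
#' @param pas_fidelity_p,pas_fidelity_d probability that the canonical
#'   AAUAAA hexamer is planted within 100 nt upstream of the proximal /
#'   distal cleavage site (a scrambled hexamer is planted otherwise).
#' @param expression_sdlog SD (log scale) of the per-gene lognormal
#'   expression multiplier.
#' @param library_size total mapped reads reported per sample in the
#'   manifest. The simulated UTRs are a small slice of a transcriptome, so
#'   the library size is a parameter rather than the within-slice coverage
#'   sum; the default of 1e6 makes RPM-normalized depth equal raw depth.
#' @param rbm3_window half-width (nt) of the window around the distal PAS in
#'   which the AAUAUA motif is planted.
#' @param seq_flank nt of background sequence appended 3' of the UTR end in
#'   the written FASTA (so distal-PAS windows are fully covered).
#' @param seed integer seed; identical configurations produce byte-identical
#'   outputs.
#'
#' @return A `sim_config` object (validated list).
#' @examples
#' cfg <- sim_config(n_genes = 10, seed = 42)
#' truth <- generate_truth(cfg)
#' @export
sim_config <- function(n_genes = 100,
                       utr_length_range = c(600L, 1500L),
                       min_pas_separation = 200L,
                       conditions = c("naive", "CD3_8h", "CD3CD28_8h",
                                      "CD3_48h", "CD3CD28_48h"),
                       n_replicates = 3L,
                       mean_depth = 30,
                       noise_model = c("poisson", "negative_binomial", "none"),
                       nb_dispersion = 0.1,
                       replicate_pdui_sd = 5,
                       frac_shortened = 0.6,
                       frac_lengthened = 0.1,
                       frac_early = 0.35,
                       frac_rbm3 = 0.5,
                       frac_cd28_enhanced = 0,
                       cd28_enhance_factor = 2.5,
                       dpdui_range = c(25, 60),
                       pas_fidelity_p = 0.4,
                       pas_fidelity_d = 0.9,
                       expression_sdlog = 0.5,
                       library_size = 1e6,
                       rbm3_window = 25L,
                       seq_flank = 200L,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    n_genes = as.integer(n_genes),
    utr_length_range = as.integer(utr_length_range),
    min_pas_separation = as.integer(min_pas_separation),
    conditions = as.character(conditions),
    n_replicates = as.integer(n_replicates),
    mean_depth = mean_depth,
    noise_model = noise_model,
    nb_dispersion = nb_dispersion,
    replicate_pdui_sd = replicate_pdui_sd,
    frac_shortened = frac_shortened,
    frac_lengthened = frac_lengthened,
    frac_early = frac_early,
    frac_rbm3 = frac_rbm3,
    frac_cd28_enhanced = frac_cd28_enhanced,
    cd28_enhance_factor = cd28_enhance_factor,
    dpdui_range = dpdui_range,
    pas_fidelity_p = pas_fidelity_p,
    pas_fidelity_d = pas_fidelity_d,
    expression_sdlog = expression_sdlog,
    library_size = library_size,
    rbm3_window = as.integer(rbm3_window),
    seq_flank = as.integer(seq_flank),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if(cfg$n_genes < 1, "n_genes must be >= 1")
  stop_if(length(cfg$utr_length_range) != 2 ||
            cfg$utr_length_range[1] > cfg$utr_length_range[2] ||
            cfg$utr_length_range[1] < 1,
          "utr_length_range must be an increasing positive pair")
  stop_if(cfg$min_pas_separation >= min(cfg$utr_length_range),
          "min_pas_separation must be smaller than the shortest UTR")
  stop_if(length(cfg$conditions) < 1 || anyDuplicated(cfg$conditions) > 0,
          "conditions must be a non-empty set of unique labels")
  stop_if(cfg$n_replicates < 1, "n_replicates must be >= 1")
  stop_if(cfg$mean_depth <= 0, "mean_depth must be positive")
  stop_if(cfg$frac_shortened < 0 || cfg$frac_lengthened < 0 ||
            cfg$frac_shortened + cfg$frac_lengthened > 1,
          "frac_shortened + frac_lengthened must lie in [0, 1]")
  for (f in c("frac_early", "frac_rbm3", "frac_cd28_enhanced",
              "pas_fidelity_p", "pas_fidelity_d")) {
    stop_if(cfg[[f]] < 0 || cfg[[f]] > 1, f, " must lie in [0, 1]")
  }
  stop_if(cfg$dpdui_range[1] <= 20 && cfg$frac_shortened + cfg$frac_lengthened > 0,
          "dpdui_range minimum must exceed 20 so planted events clear the calling threshold")
  stop_if(cfg$replicate_pdui_sd < 0, "replicate_pdui_sd must be >= 0")
  stop_if(cfg$library_size <= 0, "library_size must be positive")
  invisible(cfg)
}

#' Construct a ground-truth object by hand
#'
#' Assembles an `apa_truth` object from explicit per-gene fields, bypassing
#' the random generator. Used for targeted simulations where the true PDUI
#' and breakpoint must be set exactly (e.g. definitional checks at PDUI 0
#' and 100).
#'
#' @param config a [sim_config()] (supplies conditions, depth, noise, seed).
#' @param utr_length integer vector of UTR lengths (nt).
#' @param proximal_offset integer vector, proximal breakpoint offsets from
#'   the UTR 5' end (strictly interior).
#' @param true_pdui either a single numeric vector recycled across
#'   conditions, or a matrix (genes x conditions) of true PDUI values in
#'   \[0, 100\].
#' @param expression per-gene expression multipliers (default 1).
#' @param rbm3_regulated logical vector (default all FALSE).
#' @param strand strand per gene (default "+").
#'
#' @return An `apa_truth` object; see [generate_truth()].
#' @export
apa_truth <- function(config, utr_length, proximal_offset, true_pdui,
                      expression = 1, rbm3_regulated = FALSE,
                      strand = "+") {
  n <- length(utr_length)
  utr_length <- as.integer(utr_length)
  proximal_offset <- as.integer(rep_len(proximal_offset, n))
  stop_if(any(proximal_offset <= 0 | proximal_offset >= utr_length),
          "proximal_offset must be strictly interior to the UTR")
  conds <- config$conditions
  if (is.matrix(true_pdui)) {
    stop_if(nrow(true_pdui) != n || ncol(true_pdui) != length(conds),
            "true_pdui matrix must be genes x conditions")
    pdui_mat <- true_pdui
  } else {
    pdui_mat <- matrix(rep_len(true_pdui, n), n, length(conds))
  }
  stop_if(any(pdui_mat < 0 | pdui_mat > 100), "true_pdui must lie in [0, 100]")
  expression <- rep_len(expression, n)
  stop_if(any(expression <= 0), "expression must be positive")
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    chrom = "chrS",
    start = cumsum(c(0L, head(utr_length, -1) + 100L)),
    strand = rep_len(strand, n),
    utr_length = utr_length,
    proximal_offset = proximal_offset,
    status = "unchanged",
    early = FALSE,
    rbm3_regulated = rep_len(rbm3_regulated, n),
    cd28_enhanced = FALSE,
    expression = expression,
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + genes$utr_length
  pdui <- data.frame(
    gene_id = rep(genes$gene_id, times = length(conds)),
    condition = rep(conds, each = n),
    true_pdui = as.vector(pdui_mat),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, pdui = pdui, config = config),
            class = "apa_truth")
}

#' Generate the ground-truth table for a simulated APA experiment
#'
#' Draws per-gene UTR lengths, proximal breakpoints, expression multipliers
#' and per-condition true PDUI values. Genes destined to shorten start from
#' a long-3'UTR basal state (naive PDUI drawn Uniform(66, 100), mirroring
#' the long-UTR bias of unstimulated cells); lengthened genes start low
#' (Uniform(0, 34)); unchanged genes are drawn Uniform(20, 80). Changing
#' genes shift by a |dPDUI| drawn from `config$dpdui_range` at the late
#' time point, and already at the early time point for the `frac_early`
#' subset. CD28-enhanced genes have their shift multiplied by
#' `cd28_enhance_factor` under CD28-costimulated conditions (clamped to the
#' PDUI scale).
#'
#' @param config a [sim_config()].
#' @return An `apa_truth` object: list with `genes` (per-gene data.frame:
#'   coordinates, strand, `proximal_offset`, `status`
#'   (shortened/lengthened/unchanged), `early`, `rbm3_regulated`,
#'   `cd28_enhanced`, `expression`), `pdui` (long data.frame `gene_id`,
#'   `condition`, `true_pdui`) and the `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  L <- runif_int(n, config$utr_length_range[1], config$utr_length_range[2])

  # Proximal site at least 150 nt into the UTR so the 100-nt upstream signal
  # region is contained, and at least min_pas_separation from the distal end.
  off_lo <- 150L
  off_hi <- L - config$min_pas_separation
  stop_if(any(off_hi <= off_lo),
          "UTRs too short for the proximal-site placement rules")
  proximal <- runif_int(n, off_lo, off_hi)

  n_s <- round(config$frac_shortened * n)
  n_l <- round(config$frac_lengthened * n)
  ord <- sample.int(n)
  status <- rep("unchanged", n)
  status[ord[seq_len(n_s)]] <- "shortened"
  if (n_l > 0) status[ord[n_s + seq_len(n_l)]] <- "lengthened"

  early <- rep(FALSE, n)
  for (st in c("shortened", "lengthened")) {
    idx <- which(status == st)
    if (length(idx)) {
      k <- round(config$frac_early * length(idx))
      if (k > 0) early[sample(idx, k)] <- TRUE
    }
  }

  rbm3 <- rep(FALSE, n)
  idx_es <- which(status == "shortened" & early)
  if (length(idx_es)) {
    k <- round(config$frac_rbm3 * length(idx_es))
    if (k > 0) rbm3[sample(idx_es, k)] <- TRUE
  }

  cd28 <- rep(FALSE, n)
  idx_s <- which(status == "shortened")
  if (length(idx_s) && config$frac_cd28_enhanced > 0) {
    k <- round(config$frac_cd28_enhanced * length(idx_s))
    if (k > 0) cd28[sample(idx_s, k)] <- TRUE
  }

  expression <- rlnorm(n, 0, config$expression_sdlog)

  basal <- numeric(n)
  basal[status == "shortened"] <- runif(sum(status == "shortened"), 66, 100)
  basal[status == "lengthened"] <- runif(sum(status == "lengthened"), 0, 34)
  basal[status == "unchanged"] <- runif(sum(status == "unchanged"), 20, 80)
  delta <- runif(n, config$dpdui_range[1], config$dpdui_range[2])

  conds <- config$conditions
  pdui_mat <- matrix(basal, n, length(conds),
                     dimnames = list(NULL, conds))
  for (j in seq_along(conds)[-1]) {
    late <- grepl("48", conds[j], fixed = TRUE)
    has_cd28 <- grepl("CD28", conds[j], fixed = TRUE)
    shifts <- status != "unchanged" & (late | early)
    eff <- delta * ifelse(has_cd28 & cd28, config$cd28_enhance_factor, 1)
    val <- basal
    sh <- shifts & status == "shortened"
    lg <- shifts & status == "lengthened"
    val[sh] <- clamp(basal[sh] - eff[sh], 0, 100)
    val[lg] <- clamp(basal[lg] + eff[lg], 0, 100)
    pdui_mat[, j] <- val
  }

  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    chrom = "chrS",
    start = cumsum(c(0L, head(L, -1) + 100L)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    utr_length = L,
    proximal_offset = proximal,
    status = status,
    early = early,
    rbm3_regulated = rbm3,
    cd28_enhanced = cd28,
    expression = expression,
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + genes$utr_length

  pdui <- data.frame(
    gene_id = rep(genes$gene_id, times = length(conds)),
    condition = rep(conds, each = n),
    true_pdui = as.vector(pdui_mat),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, pdui = pdui, config = config),
            class = "apa_truth")
}

#' @export
print.apa_truth <- function(x, ...) {
  cat(sprintf("apa_truth: %d genes x %d conditions (seed %d)\n",
              nrow(x$genes), length(x$config$conditions), x$config$seed))
  print(table(x$genes$status))
  invisible(x)
}

#' Write the ground-truth table as TSV
#'
#' Long format, one row per gene and condition, with columns
#' `gene_id utr_length proximal_offset condition true_pdui expression
#' rbm3_regulated`.
#'
#' @param truth an `apa_truth` object.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  g <- truth$genes
  m <- merge(truth$pdui,
             g[, c("gene_id", "utr_length", "proximal_offset",
                   "expression", "rbm3_regulated")],
             by = "gene_id", sort = FALSE)
  m <- m[order(m$gene_id, match(m$condition, truth$config$conditions)),
         c("gene_id", "utr_length", "proximal_offset", "condition",
           "true_pdui", "expression", "rbm3_regulated")]
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# One scrambled permutation of AATAAA (T moved off its canonical position),
# guaranteed not to equal the core hexamer.
scrambled_hexamer <- function() {
  pos <- sample(c(1, 2, 4, 5, 6), 1)
  x <- rep("A", 6)
  x[pos] <- "T"
  paste(x, collapse = "")
}

# Remove every AATAAA occurrence lying fully within the 0-based positions
# [lo, hi] of a character-vector sequence by mutating the hexamer's T to C.
# Keeps the planted signal incidence exact at non-planted sites: without
# this, a scrambled hexamer (five A, one T) can recombine with flanking
# background A's into a spurious canonical signal.
scrub_hexamer <- function(s, lo, hi) {
  lo <- max(lo, 0L)
  hi <- min(hi, length(s) - 1L)
  repeat {
    region <- paste(s[(lo + 1):(hi + 1)], collapse = "")
    m <- regexpr("AATAAA", region, fixed = TRUE)
    if (m == -1) break
    s[lo + as.integer(m) + 2L] <- "C"   # the T of the matched hexamer
  }
  s
}

#' Write BED annotation and planted FASTA sequences for a simulated truth
#'
#' Emits one BED6 record per gene (0-based half-open, strand-aware) and one
#' FASTA record per gene holding the transcript-oriented UTR sequence plus a
#' 3' flank of `config$seq_flank` nt. Background composition is uniform over
#' A/C/G/T. The canonical polyadenylation hexamer AATAAA (AAUAAA on the
#' transcript) is planted at a uniform position fully within the 100 nt
#' upstream of the proximal site with probability `pas_fidelity_p` (a
#' scrambled non-matching hexamer is planted otherwise), and likewise at the
#' distal site with `pas_fidelity_d`. Non-planted signal regions are scrubbed
#' of chance AATAAA occurrences so that rescanning the written FASTA
#' reproduces the planted signal incidence exactly. For RBM3-regulated genes
#' an AATATA (AAUAUA) is planted within `rbm3_window` nt of the distal
#' cleavage position, avoiding the planted distal hexamer.
#'
#' Minus-strand genes are represented genomically by the BED strand field;
#' their FASTA record stores the transcript orientation (i.e. the reverse
#' complement of the genomic plus strand), so "upstream" always means 5' on
#' the transcript.
#'
#' @param truth an `apa_truth` object.
#' @param outdir output directory (created if needed).
#' @param bed,fasta file names inside `outdir`.
#' @return Invisibly, a list with the two paths and the `DNAStringSet`.
#' @export
write_annotation_and_sequence <- function(truth, outdir,
                                          bed = "utr.bed",
                                          fasta = "utr.fa") {
  stopifnot(inherits(truth, "apa_truth"))
  stop_if(nrow(truth$genes) == 0, "truth is empty")
  cfg <- truth$config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)

  g <- truth$genes
  seqs <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    L <- g$utr_length[i]
    slen <- L + cfg$seq_flank
    s <- sample(c("A", "C", "G", "T"), slen, replace = TRUE)

    plant <- function(s, motif, start0) {
      chars <- strsplit(motif, "")[[1]]
      s[(start0 + 1):(start0 + length(chars))] <- chars
      s
    }
    # proximal PAS signal region: fully within 100 nt upstream of the site
    p_off <- g$proximal_offset[i]
    p_planted <- runif(1) < cfg$pas_fidelity_p
    hex_p <- if (p_planted) "AATAAA" else scrambled_hexamer()
    s <- plant(s, hex_p, sample(seq(p_off - 100L, p_off - 6L), 1))
    # distal PAS signal region: upstream of the annotated UTR end
    d_planted <- runif(1) < cfg$pas_fidelity_d
    hex_d <- if (d_planted) "AATAAA" else scrambled_hexamer()
    d_start <- sample(seq(L - 100L, L - 6L), 1)
    s <- plant(s, hex_d, d_start)
    if (g$rbm3_regulated[i]) {
      w <- cfg$rbm3_window
      for (try in 1:50) {
        r_start <- sample(seq(L - w, L + w - 6L), 1)
        if (r_start + 5L < d_start || r_start > d_start + 5L) break
        r_start <- L  # always clear of the distal hexamer (which ends < L)
      }
      s <- plant(s, "AATATA", r_start)
    }
    # non-planted signal regions must carry no canonical hexamer at all
    if (!p_planted) s <- scrub_hexamer(s, p_off - 100L, p_off - 1L)
    if (!d_planted) s <- scrub_hexamer(s, L - 100L, L - 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- g$gene_id
  fasta_path <- file.path(outdir, fasta)
  Biostrings::writeXStringSet(dna, fasta_path)

  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$name <- g$gene_id
  S4Vectors::mcols(gr)$score <- 0L
  bed_path <- file.path(outdir, bed)
  rtracklayer::export(gr, bed_path, format = "BED")

  invisible(list(bed = bed_path, fasta = fasta_path, sequences = dna))
}

#' Simulate replicate coverage tracks from a ground truth
#'
#' Realizes the two-isoform coverage model. For gene \eqn{g}, sample
#' \eqn{s} of condition \eqn{c}, the replicate-level PDUI is
#' \eqn{p = \mathrm{truePDUI}(g,c) + N(0, \sigma)} truncated to \[0, 100\],
#' and the expected raw depth at transcript position \eqn{x} is
#' \deqn{\lambda(x) = \mathrm{depth} \cdot \mathrm{expr}_g \cdot
#'   [\, p/100 + (1 - p/100)\,\mathbf{1}(x < \mathrm{offset}_g)\,],}
#' i.e. constant over the full UTR for the long isoform plus an additional
#' step upstream of the proximal breakpoint for the short isoform.
#' Positional noise follows `config$noise_model`.
#'
#' @param truth an `apa_truth` object (carries its `sim_config`).
#' @param outdir if non-NULL, one bedGraph per sample
#'   (`{condition}_{replicate}.bedGraph`, genomic orientation, zero runs
#'   omitted) and a `samples.tsv` manifest
#'   (`sample_id condition replicate total_mapped_reads path`) are written
#'   there.
#' @return An `apa_coverage` object: list with `samples` (data.frame),
#'   `depth` (named list, one `utr_length x n_samples` matrix of raw depth
#'   per gene, transcript orientation), `genes`, and `normalized = FALSE`.
#' @export
simulate_coverage <- function(truth, outdir = NULL) {
  stopifnot(inherits(truth, "apa_truth"))
  cfg <- truth$config
  set.seed(cfg$seed + 2L)
  g <- truth$genes
  n <- nrow(g)
  conds <- cfg$conditions
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         condition = conds,
                         KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate")]
  samples$sample_id <- paste(samples$condition, samples$replicate, sep = "_")
  samples$total_mapped_reads <- cfg$library_size
  samples$path <- NA_character_

  pdui_lookup <- matrix(NA_real_, n, length(conds),
                        dimnames = list(g$gene_id, conds))
  pdui_lookup[cbind(match(truth$pdui$gene_id, g$gene_id),
                    match(truth$pdui$condition, conds))] <- truth$pdui$true_pdui

  depth <- lapply(seq_len(n), function(i)
    matrix(0, g$utr_length[i], nrow(samples),
           dimnames = list(NULL, samples$sample_id)))
  names(depth) <- g$gene_id

  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    grl <- vector("list", n)
    for (i in seq_len(n)) {
      L <- g$utr_length[i]
      p <- pdui_lookup[i, cond]
      if (cfg$replicate_pdui_sd > 0) {
        p <- clamp(p + rnorm(1, 0, cfg$replicate_pdui_sd), 0, 100)
      }
      pfrac <- p / 100
      hi <- cfg$mean_depth * g$expression[i]
      lambda <- c(rep(hi, g$proximal_offset[i]),
                  rep(hi * pfrac, L - g$proximal_offset[i]))
      d <- switch(cfg$noise_model,
                  none = lambda,
                  poisson = rpois(L, lambda),
                  negative_binomial = rnbinom(L, mu = lambda,
                                              size = 1 / cfg$nb_dispersion))
      depth[[i]][, s] <- d
      if (!is.null(outdir)) {
        genomic <- if (g$strand[i] == "-") rev(d) else d
        grl[[i]] <- depth_runs_granges(g$chrom[i], g$start[i], genomic)
      }
    }
    if (!is.null(outdir)) {
      gr <- do.call(c, grl[!vapply(grl, is.null, logical(1))])
      path <- file.path(outdir, paste0(samples$sample_id[s], ".bedGraph"))
      rtracklayer::export(gr, path, format = "bedGraph")
      samples$path[s] <- path
    }
  }
  if (!is.null(outdir)) {
    write.table(samples[, c("sample_id", "condition", "replicate",
                            "total_mapped_reads", "path")],
                file.path(outdir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(samples = samples, depth = depth, genes = g,
                 normalized = FALSE),
            class = "apa_coverage")
}

#' @export
print.apa_coverage <- function(x, ...) {
  cat(sprintf("apa_coverage: %d genes x %d samples (%s)\n",
              length(x$depth), nrow(x$samples),
              if (isTRUE(x$normalized)) "RPM" else "raw"))
  invisible(x)
}
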