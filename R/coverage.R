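# Reading, normalizing and aggregating per-base 3'UTR coverage.

#' Read a BED6 file of 3'UTR annotations
#'
#' The BED `name` field must hold a unique gene identifier. Coordinates are
#' kept 0-based half-open. The distal cleavage site is the transcript 3'
#' terminus: the `end` coordinate on plus-strand genes, `start` on minus.
#'
#' @param path BED6 file.
#' @return A `utr_annotation` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `utr_length`, `distal_site`.
#' @export
read_utr_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED file '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  name <- S4Vectors::mcols(gr)$name
  stop_if(is.null(name) || anyNA(name),
          "BED name field (column 4) must hold gene identifiers")
  dup <- unique(name[duplicated(name)])
  stop_if(length(dup) > 0,
          "duplicated gene_id in BED name field: ",
          paste(head(dup, 5), collapse = ", "))
  strand <- as.character(GenomicRanges::strand(gr))
  stop_if(any(!strand %in% c("+", "-")),
          "every BED record needs an explicit +/- strand")
  anno <- data.frame(
    gene_id = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  anno$utr_length <- anno$end - anno$start
  stop_if(any(anno$utr_length <= 0), "BED records must satisfy start < end")
  anno$distal_site <- ifelse(anno$strand == "+", anno$end, anno$start)
  class(anno) <- c("utr_annotation", "data.frame")
  anno
}

#' Construct a single coverage track
#'
#' A per-base depth vector over one gene's 3'UTR for one sample, stored in
#' transcript orientation (`depth[1]` is the 5'-most UTR base).
#'
#' @param gene_id gene identifier.
#' @param depth non-negative numeric vector, one value per UTR base.
#' @param sample_id,condition,replicate sample metadata.
#' @param normalized whether `depth` is already in RPM units.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(gene_id, depth, sample_id = NA_character_,
                           condition = NA_character_,
                           replicate = NA_integer_, normalized = FALSE) {
  stop_if(any(depth < 0), "coverage depth must be non-negative")
  structure(list(gene_id = gene_id, sample_id = sample_id,
                 condition = condition, replicate = replicate,
                 depth = as.numeric(depth), normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s / %s: %d nt, mean depth %.3g (%s)\n",
              x$gene_id, x$sample_id, length(x$depth), mean(x$depth),
              if (isTRUE(x$normalized)) "RPM" else "raw"))
  invisible(x)
}

#' Load per-gene coverage from a bedGraph file
#'
#' Expands bedGraph intervals (value constant over the interval) to a dense
#' per-base vector over each annotated UTR. Positions with no bedGraph
#' record get depth 0. Minus-strand genes are flipped into transcript
#' orientation.
#'
#' @param path 4-column bedGraph file.
#' @param annotations a `utr_annotation` data.frame from [read_utr_bed()].
#' @param sample_id,condition,replicate metadata attached to every track;
#'   by default parsed from the file name `{condition}_{replicate}.bedGraph`.
#' @return Named list (by gene) of `coverage_track` objects (raw units).
#' @export
load_coverage <- function(path, annotations, sample_id = NULL,
                          condition = NULL, replicate = NULL) {
  base <- tools::file_path_sans_ext(basename(path))
  if (is.null(sample_id)) sample_id <- base
  if (is.null(condition) || is.null(replicate)) {
    m <- regmatches(base, regexec("^(.*)_([0-9]+)$", base))[[1]]
    if (length(m) == 3) {
      if (is.null(condition)) condition <- m[2]
      if (is.null(replicate)) replicate <- as.integer(m[3])
    }
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  score <- S4Vectors::mcols(gr)$score
  stop_if(any(score < 0), "bedGraph intervals with negative values in ", path)

  anno_gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end))
  hits <- GenomicRanges::findOverlaps(anno_gr, gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  gr_start <- GenomicRanges::start(gr)
  gr_end <- GenomicRanges::end(gr)
  hit_idx <- split(sh, factor(qh, levels = seq_len(nrow(annotations))))

  out <- vector("list", nrow(annotations))
  names(out) <- annotations$gene_id
  for (i in seq_len(nrow(annotations))) {
    L <- annotations$utr_length[i]
    d <- numeric(L)
    js <- hit_idx[[i]]
    lo <- pmax(gr_start[js], annotations$start[i] + 1L) - annotations$start[i]
    hi <- pmin(gr_end[js], annotations$end[i]) - annotations$start[i]
    if (length(js)) {
      d[sequence(hi - lo + 1L, from = lo)] <- rep(score[js], hi - lo + 1L)
    }
    if (annotations$strand[i] == "-") d <- rev(d)
    out[[i]] <- coverage_track(annotations$gene_id[i], d,
                               sample_id = sample_id,
                               condition = condition %||% NA_character_,
                               replicate = replicate %||% NA_integer_)
  }
  out
}

#' Normalize a coverage track to reads per million
#'
#' Scales depth by `1e6 / total_mapped_reads` (per-sample library size).
#'
#' @param track a `coverage_track` (raw units).
#' @param total_mapped_reads positive library size for the track's sample.
#' @return The track with RPM depth and `normalized = TRUE`.
#' @export
normalize_rpm <- function(track, total_mapped_reads) {
  stopifnot(inherits(track, "coverage_track"))
  stop_if(isTRUE(track$normalized), "track is already normalized")
  stop_if(!is.numeric(total_mapped_reads) || length(total_mapped_reads) != 1 ||
            total_mapped_reads <= 0,
          "total_mapped_reads must be a single positive number")
  track$depth <- track$depth * 1e6 / total_mapped_reads
  track$normalized <- TRUE
  track
}

#' Average replicate coverage tracks position-wise
#'
#' All tracks must cover the same gene, be normalized, and have equal
#' length. The result keeps the condition label with the replicate index
#' cleared.
#'
#' @param tracks list of normalized `coverage_track` objects (same gene and
#'   condition).
#' @return A `coverage_track` holding the position-wise mean.
#' @export
average_replicates <- function(tracks) {
  stop_if(length(tracks) < 1, "need at least one track")
  stopifnot(all(vapply(tracks, inherits, logical(1), "coverage_track")))
  genes <- unique(vapply(tracks, `[[`, character(1), "gene_id"))
  stop_if(length(genes) != 1, "tracks cover different genes: ",
          paste(genes, collapse = ", "))
  stop_if(!all(vapply(tracks, `[[`, logical(1), "normalized")),
          "all tracks must be normalized before averaging")
  lens <- vapply(tracks, function(t) length(t$depth), integer(1))
  stop_if(length(unique(lens)) != 1, "tracks have unequal lengths")
  m <- vapply(tracks, `[[`, numeric(lens[1]), "depth")
  coverage_track(genes, rowMeans(as.matrix(m)),
                 sample_id = NA_character_,
                 condition = tracks[[1]]$condition,
                 replicate = NA_integer_, normalized = TRUE)
}

#' Read a sample manifest TSV
#'
#' Columns `sample_id condition replicate total_mapped_reads path`.
#'
#' @param path manifest file.
#' @return data.frame.
#' @export
read_sample_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "total_mapped_reads", "path")
  miss <- setdiff(need, names(m))
  stop_if(length(miss) > 0, "manifest missing columns: ",
          paste(miss, collapse = ", "))
  stop_if(any(m$total_mapped_reads <= 0),
          "total_mapped_reads must be positive for every sample")
  m
}

#' Load and normalize a full coverage set from a manifest
#'
#' Reads every sample's bedGraph, RPM-normalizes it by the manifest's
#' per-sample library size, and assembles per-gene depth matrices
#' (transcript orientation, one column per sample).
#'
#' @param manifest manifest data.frame ([read_sample_manifest()]) or path.
#' @param annotations a `utr_annotation` data.frame.
#' @return An `apa_coverage` object (see [simulate_coverage()]) with
#'   `normalized = TRUE`.
#' @export
load_coverage_set <- function(manifest, annotations) {
  if (is.character(manifest)) manifest <- read_sample_manifest(manifest)
  depth <- lapply(seq_len(nrow(annotations)), function(i)
    matrix(0, annotations$utr_length[i], nrow(manifest),
           dimnames = list(NULL, manifest$sample_id)))
  names(depth) <- annotations$gene_id
  for (s in seq_len(nrow(manifest))) {
    tracks <- load_coverage(manifest$path[s], annotations,
                            sample_id = manifest$sample_id[s],
                            condition = manifest$condition[s],
                            replicate = manifest$replicate[s])
    for (gid in names(tracks)) {
      tr <- normalize_rpm(tracks[[gid]], manifest$total_mapped_reads[s])
      depth[[gid]][, s] <- tr$depth
    }
  }
  structure(list(samples = manifest, depth = depth,
                 genes = as.data.frame(annotations), normalized = TRUE),
            class = "apa_coverage")
}

#' RPM-normalize an in-memory coverage set
#'
#' Column-scales every per-gene depth matrix by `1e6 / total_mapped_reads`
#' of the corresponding sample.
#'
#' @param cov an `apa_coverage` object with raw depth.
#' @return The set with RPM depth and `normalized = TRUE`.
#' @export
normalize_coverage_set <- function(cov) {
  stopifnot(inherits(cov, "apa_coverage"))
  stop_if(isTRUE(cov$normalized), "coverage set is already normalized")
  fac <- 1e6 / cov$samples$total_mapped_reads
  cov$depth <- lapply(cov$depth, function(m) sweep(m, 2, fac, `*`))
  cov$normalized <- TRUE
  cov
}

#' Write per-condition replicate-averaged coverage as bedGraph
#'
#' Produces a browser-style track: RPM depth averaged across replicates of
#' one condition, written in genomic orientation with zero runs omitted.
#'
#' @param cov a normalized `apa_coverage` object.
#' @param condition condition label to average.
#' @param path output bedGraph path.
#' @return The path, invisibly.
#' @export
write_condition_bedgraph <- function(cov, condition, path) {
  stopifnot(inherits(cov, "apa_coverage"), isTRUE(cov$normalized))
  idx <- which(cov$samples$condition == condition)
  stop_if(length(idx) == 0, "no samples for condition ", condition)
  g <- cov$genes
  grl <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    d <- rowMeans(cov$depth[[g$gene_id[i]]][, idx, drop = FALSE])
    if (g$strand[i] == "-") d <- rev(d)
    grl[[i]] <- depth_runs_granges(g$chrom[i], g$start[i], d)
  }
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
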