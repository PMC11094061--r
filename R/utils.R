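# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# Integer draw, uniform on lo..hi inclusive (vectorized over lo/hi).
runif_int <- function(n, lo, hi) {
  as.integer(floor(runif(n, lo, hi + 1)))
}

# Collapse a per-base depth vector (genomic orientation, 0-based start) into
# a GRanges of constant-value runs, dropping zero runs (absent = 0 in
# bedGraph semantics).
depth_runs_granges <- function(chrom, start0, depth) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L      # 1-based within vector
  keep <- r$values != 0
  if (!any(keep)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + starts[keep],
                              end = start0 + ends[keep])
  )
  S4Vectors::mcols(gr)$score <- r$values[keep]
  gr
}

# Write a data.frame as TSV with '# key: value' header lines.
write_tsv_header <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(x) paste(format(x), collapse = ","),
                              character(1))), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

# DNA -> RNA alphabet, uppercased.
dna_to_rna <- function(x) chartr("acgtT", "ACGUU", x)
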