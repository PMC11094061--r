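# Gene-set overlap (overrepresentation) testing.

#' Read a gene list file
#'
#' One identifier per line; `#` starts a comment; blank lines and
#' duplicates are dropped.
#'
#' @param path text file.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Tests whether `query_genes` overlap `set_genes` more than expected by
#' chance when drawing from `background_genes`. The p-value is the
#' one-sided hypergeometric upper tail (including the observed overlap),
#' equivalent to a one-sided Fisher exact test. Fold enrichment is
#' `(overlap/query) / (set/background)`. The query must be a subset of the
#' background; the annotation set is intersected with the background before
#' testing. The default pass filter mirrors the common overrepresentation
#' convention: p < `alpha` and fold enrichment > `min_fold`.
#'
#' @param query_genes,set_genes,background_genes character vectors
#'   (deduplicated internally).
#' @param alpha,min_fold filter thresholds.
#' @return One-row data.frame: `query_n`, `set_n`, `overlap_n`,
#'   `background_n`, `fold_enrichment`, `odds_ratio`, `p_value`,
#'   `passes_filter`.
#' @export
overlap_enrichment <- function(query_genes, set_genes, background_genes,
                               alpha = 0.05, min_fold = 2) {
  query <- unique(query_genes)
  bg <- unique(background_genes)
  outside <- setdiff(query, bg)
  stop_if(length(outside) > 0,
          "query genes missing from background: ",
          paste(head(outside, 10), collapse = ", "),
          if (length(outside) > 10) ", ..." else "")
  set <- intersect(unique(set_genes), bg)
  N <- length(bg)
  K <- length(set)
  n <- length(query)
  k <- length(intersect(query, set))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  a <- k; b <- n - k; cc <- K - k; d <- N - K - b
  odds <- if (b > 0 && cc > 0) (a * d) / (b * cc) else Inf
  data.frame(query_n = n, set_n = K, overlap_n = k, background_n = N,
             fold_enrichment = fold, odds_ratio = odds, p_value = p,
             passes_filter = !is.na(fold) && p < alpha && fold > min_fold)
}

#' Batch overlap enrichment with BH adjustment
#'
#' Runs [overlap_enrichment()] for every (query, annotation set) pair and
#' adjusts p-values by Benjamini-Hochberg across the annotation sets within
#' each query.
#'
#' @param query_sets,annotation_sets named lists of gene-id vectors.
#' @param background_genes common background.
#' @param alpha,min_fold filter thresholds (the filter uses the adjusted p).
#' @return data.frame, one row per pair, with `query`, `set`, the
#'   [overlap_enrichment()] columns, and `p_adj`.
#' @export
batch_enrichment <- function(query_sets, annotation_sets, background_genes,
                             alpha = 0.05, min_fold = 2) {
  stop_if(is.null(names(query_sets)) || is.null(names(annotation_sets)),
          "query_sets and annotation_sets must be named lists")
  out <- list()
  for (q in names(query_sets)) {
    rows <- do.call(rbind, lapply(names(annotation_sets), function(s) {
      r <- overlap_enrichment(query_sets[[q]], annotation_sets[[s]],
                              background_genes, alpha, min_fold)
      cbind(data.frame(query = q, set = s, stringsAsFactors = FALSE), r)
    }))
    rows$p_adj <- p.adjust(rows$p_value, method = "BH")
    rows$passes_filter <- !is.na(rows$fold_enrichment) &
      rows$p_adj < alpha & rows$fold_enrichment > min_fold
    out[[q]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
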