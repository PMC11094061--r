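# PAS-strength scoring and positional motif density maps around cleavage
# sites.

#' Build the PAS site table from fitted breakpoints and annotations
#'
#' For every gene with a fitted breakpoint the proximal PAS is the fitted
#' offset; the distal PAS is the annotated UTR 3' end (transcript offset =
#' UTR length). A user-supplied override table (e.g. proximal sites
#' validated by an independent algorithm) replaces the fitted proximal
#' offsets for the genes it lists.
#'
#' @param fits named list of `pdui_fit` objects or a data.frame with
#'   `gene_id` and `breakpoint`.
#' @param utr_lengths named vector of UTR lengths (nt) by gene, or a
#'   `utr_annotation` data.frame.
#' @param override optional data.frame `gene_id`, `breakpoint` of proximal
#'   sites to use instead of the fitted ones.
#' @return data.frame `gene_id`, `site`, `site_kind` (transcript offsets).
#' @export
pas_sites <- function(fits, utr_lengths, override = NULL) {
  if (is.data.frame(utr_lengths)) {
    utr_lengths <- setNames(utr_lengths$utr_length, utr_lengths$gene_id)
  }
  if (!is.data.frame(fits)) {
    fits <- data.frame(
      gene_id = vapply(fits, `[[`, character(1), "gene_id"),
      breakpoint = vapply(fits, function(f)
        as.integer(f$breakpoint %||% NA_integer_), integer(1)),
      stringsAsFactors = FALSE)
  }
  if (!is.null(override)) {
    i <- match(override$gene_id, fits$gene_id)
    miss <- is.na(i)
    fits$breakpoint[i[!miss]] <- override$breakpoint[!miss]
    if (any(miss)) {
      fits <- rbind(fits, override[miss, c("gene_id", "breakpoint")])
    }
  }
  fits <- fits[!is.na(fits$breakpoint), , drop = FALSE]
  rbind(
    data.frame(gene_id = fits$gene_id, site = fits$breakpoint,
               site_kind = "pPAS", stringsAsFactors = FALSE),
    data.frame(gene_id = fits$gene_id,
               site = as.integer(utr_lengths[fits$gene_id]),
               site_kind = "dPAS", stringsAsFactors = FALSE))
}

#' Extract sequence windows around PAS coordinates
#'
#' Slices `[site - flank_up, site + flank_down)` (transcript coordinates,
#' 0-based; the cleavage position is offset 0) out of per-gene
#' transcript-oriented sequences, transliterating DNA T to RNA U. Windows
#' that would run past the available sequence are truncated and flagged.
#'
#' @param sites data.frame `gene_id`, `site`, `site_kind` (see
#'   [pas_sites()]).
#' @param sequences a `DNAStringSet`/`RNAStringSet` or named character
#'   vector keyed by gene id, holding the transcript-oriented UTR (+ 3'
#'   flank) sequence of each gene, as written by
#'   [write_annotation_and_sequence()].
#' @param flank_up,flank_down nt kept upstream / downstream of the site.
#' @return A `pas_windows` data.frame: `gene_id`, `site_kind`, `sequence`
#'   (RNA alphabet), `site_offset` (0-based index of the cleavage position
#'   within `sequence`), `truncated`.
#' @export
extract_pas_windows <- function(sites, sequences, flank_up = 200L,
                                flank_down = 100L) {
  seqs <- setNames(as.character(sequences), names(sequences))
  miss <- setdiff(unique(sites$gene_id), names(seqs))
  stop_if(length(miss) > 0, "no sequence for gene(s): ",
          paste(head(miss, 5), collapse = ", "))
  n <- nrow(sites)
  sequence <- character(n)
  site_offset <- integer(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    s <- seqs[[sites$gene_id[i]]]
    slen <- nchar(s)
    site <- sites$site[i]
    lo <- site - flank_up            # 0-based inclusive
    hi <- site + flank_down          # 0-based exclusive
    lo_c <- max(lo, 0L)
    hi_c <- min(hi, slen)
    truncated[i] <- lo_c > lo || hi_c < hi
    if (truncated[i]) {
      warning("PAS window truncated for ", sites$gene_id[i], " (",
              sites$site_kind[i], ")", call. = FALSE)
    }
    sequence[i] <- dna_to_rna(substr(s, lo_c + 1L, hi_c))
    site_offset[i] <- site - lo_c
  }
  out <- data.frame(gene_id = sites$gene_id, site_kind = sites$site_kind,
                    sequence = sequence, site_offset = site_offset,
                    truncated = truncated, stringsAsFactors = FALSE)
  class(out) <- c("pas_windows", "data.frame")
  out
}

# Match start offsets (relative to the cleavage position) of `motif` in a
# window, dropping any occurrence whose leading k-mer equals `exclude`.
motif_offsets <- function(sequence, site_offset, motif, exclude = NULL) {
  hits <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  if (!is.null(exclude) && nzchar(exclude)) {
    kept <- vapply(hits, function(i)
      substr(sequence, i, i + nchar(exclude) - 1L) != exclude, logical(1))
    hits <- hits[kept]
  }
  as.integer(hits - 1L - site_offset)
}

#' Scan for polyadenylation signal elements upstream of cleavage sites
#'
#' Reports, per window, whether the core PAS hexamer AAUAAA and the
#' upstream CFI enhancer element UGUA occur entirely within the `flank` nt
#' strictly upstream of the cleavage position. Windows covering less than
#' `flank` nt upstream are evaluated on the available span and flagged.
#'
#' @param windows a `pas_windows` data.frame.
#' @param flank upstream extent (nt) of the search region.
#' @return `windows` with added logical columns `has_AAUAAA`, `has_UGUA`
#'   and `flank_short` (evaluated span was shorter than `flank`).
#' @export
pas_signal_presence <- function(windows, flank = 100L) {
  region <- substr(windows$sequence,
                   pmax(windows$site_offset - flank + 1L, 1L),
                   windows$site_offset)
  windows$has_AAUAAA <- grepl("AAUAAA", region, fixed = TRUE)
  windows$has_UGUA <- grepl("UGUA", region, fixed = TRUE)
  windows$flank_short <- windows$site_offset < flank
  windows
}

#' Summarize PAS signal strength by site kind
#'
#' Fraction of proximal and distal PAS windows carrying the core AAUAAA
#' hexamer (and the UGUA element) within `flank` nt upstream of the
#' cleavage site. Windows are deduplicated by gene and site kind; an
#' optional gene-id filter restricts the event set (e.g. to events
#' cross-validated by a second algorithm).
#'
#' @param windows a `pas_windows` data.frame.
#' @param event_filter optional character vector of gene ids to keep (an
#'   empty vector yields a zero-count table, not an error).
#' @param flank upstream search extent (nt).
#' @return data.frame `site_kind`, `n`, `frac_AAUAAA`, `frac_UGUA`.
#' @export
pas_strength_summary <- function(windows, event_filter = NULL, flank = 100L) {
  if (!is.null(event_filter)) {
    windows <- windows[windows$gene_id %in% event_filter, , drop = FALSE]
  }
  windows <- windows[!duplicated(windows[, c("gene_id", "site_kind")]), ,
                     drop = FALSE]
  kinds <- c("pPAS", "dPAS")
  if (nrow(windows) == 0) {
    return(data.frame(site_kind = kinds, n = 0L,
                      frac_AAUAAA = NA_real_, frac_UGUA = NA_real_))
  }
  w <- pas_signal_presence(windows, flank = flank)
  do.call(rbind, lapply(kinds, function(k) {
    wk <- w[w$site_kind == k, , drop = FALSE]
    data.frame(site_kind = k, n = nrow(wk),
               frac_AAUAAA = if (nrow(wk)) mean(wk$has_AAUAAA) else NA_real_,
               frac_UGUA = if (nrow(wk)) mean(wk$has_UGUA) else NA_real_)
  }))
}

#' Positional motif density map around PAS coordinates
#'
#' For each offset `o` in `span` (offset 0 = cleavage position), the raw
#' fraction is the proportion of events whose 10-nt window
#' `[o, o + window_nt)` contains at least one exact occurrence of `motif`
#' (an event counts once per offset regardless of multiple matches).
#' Occurrences whose leading 6-mer equals `exclude` (the core PAS hexamer
#' by default) are never counted — a no-op for the literal AAUAUA motif but
#' meaningful for user-supplied degenerate patterns. The smoothed profile
#' is a centered running mean over `smooth_nt` offsets, with shrinking
#' windows at the span edges. Offsets whose sliding window extends past the
#' available sequence are evaluated on the intersection.
#'
#' @param windows a `pas_windows` data.frame (typically one site kind);
#'   duplicated gene/site combinations are dropped.
#' @param motif target motif (RNA alphabet), default the RBM3 hexamer.
#' @param exclude occurrences equal to this k-mer are ignored.
#' @param window_nt sliding-window width (nt).
#' @param smooth_nt running-mean width (offsets).
#' @param span integer pair, inclusive offset range relative to the site.
#' @return A `motif_profile` data.frame: `offset`, `raw_fraction`,
#'   `smoothed_fraction`, with attributes `n_events`, `motif`, `window_nt`,
#'   `smooth_nt`.
#' @export
motif_positional_map <- function(windows, motif = "AAUAUA",
                                 exclude = "AAUAAA", window_nt = 10L,
                                 smooth_nt = 5L, span = c(-100L, 100L)) {
  stop_if(nchar(motif) > window_nt,
          "motif longer than the sliding window")
  windows <- windows[!duplicated(windows[, c("gene_id", "site_kind")]), ,
                     drop = FALSE]
  offsets <- seq.int(span[1], span[2])
  n_events <- nrow(windows)
  counts <- integer(length(offsets))
  mlen <- nchar(motif)
  if (n_events > 0) {
    for (i in seq_len(n_events)) {
      starts <- motif_offsets(windows$sequence[i], windows$site_offset[i],
                              motif, exclude)
      if (!length(starts)) next
      # a match starting at t is inside window [o, o+window_nt) for
      # o in [t - window_nt + mlen, t]
      cover <- unique(unlist(lapply(starts, function(t)
        seq.int(t - window_nt + mlen, t))))
      cover <- cover[cover >= span[1] & cover <= span[2]]
      counts[cover - span[1] + 1L] <- counts[cover - span[1] + 1L] + 1L
    }
  }
  raw <- if (n_events > 0) counts / n_events else rep(NA_real_, length(offsets))
  half <- (smooth_nt - 1L) %/% 2L
  smoothed <- vapply(seq_along(raw), function(i)
    mean(raw[max(1L, i - half):min(length(raw), i + half)]), numeric(1))
  out <- data.frame(offset = offsets, raw_fraction = raw,
                    smoothed_fraction = smoothed)
  attr(out, "n_events") <- n_events
  attr(out, "motif") <- motif
  attr(out, "window_nt") <- window_nt
  attr(out, "smooth_nt") <- smooth_nt
  class(out) <- c("motif_profile", "data.frame")
  out
}

#' Motif profiles per event group and site kind
#'
#' Computes one positional motif map for every combination of a named gene
#' group (e.g. shortened at 8 h, shortened at 48 h only, non-changing) and
#' site kind present in the windows. Empty groups yield rows with
#' `n_events = 0` and NA fractions rather than an error.
#'
#' @param windows a `pas_windows` data.frame covering all groups.
#' @param groups named list of gene-id vectors.
#' @param ... passed to [motif_positional_map()].
#' @return Long data.frame `group`, `site_kind`, `offset`, `raw_fraction`,
#'   `smoothed_fraction`, `n_events`.
#' @export
compare_profiles <- function(windows, groups, ...) {
  stop_if(is.null(names(groups)) || any(names(groups) == ""),
          "groups must be a named list of gene-id vectors")
  kinds <- unique(windows$site_kind)
  out <- list()
  for (g in names(groups)) {
    for (k in kinds) {
      w <- windows[windows$gene_id %in% groups[[g]] &
                     windows$site_kind == k, , drop = FALSE]
      prof <- motif_positional_map(w, ...)
      out[[length(out) + 1L]] <- data.frame(
        group = g, site_kind = k, prof,
        n_events = attr(prof, "n_events"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("motif_profile: %s over %d events, offsets %d..%d\n",
              attr(x, "motif"), attr(x, "n_events"),
              min(x$offset), max(x$offset)))
  invisible(x)
}
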