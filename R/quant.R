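# De novo proximal-PAS breakpoint fitting and PDUI event testing.

#' Fit the two-segment coverage model for one gene
#'
#' Models the per-base depth of sample \eqn{s} as
#' \deqn{d_s(x) \approx w_{L,s} + w_{S,s}\,\mathbf{1}(x < b)}
#' where \eqn{w_L} is the long-isoform abundance (covering the full UTR),
#' \eqn{w_S} the short-isoform abundance (covering only positions upstream
#' of the breakpoint \eqn{b}), both constrained non-negative. For every
#' candidate breakpoint in `[search_min, L - search_min]` the non-negative
#' least-squares solution is closed form: with segment means \eqn{m_1}
#' (upstream) and \eqn{m_2} (downstream), \eqn{w_L = m_2},
#' \eqn{w_S = m_1 - m_2} when \eqn{m_1 \ge m_2}, else the short-isoform
#' weight is clamped to zero and the flat model refitted. The breakpoint is
#' chosen jointly: the candidate minimizing the residual sum of squares
#' summed over all samples (a single shared proximal PAS per gene). Ties
#' are broken toward the most distal candidate, which is deterministic and
#' biases against spurious shortening calls.
#'
#' The per-sample PDUI is \eqn{100\,w_L/(w_L + w_S)}: 100 when coverage is
#' flat (distal site only), 0 when coverage drops to zero at the breakpoint
#' (proximal site only).
#'
#' Quality flags: `low_coverage` if no sample reaches `min_mean_depth`
#' (no fit is attempted); `no_breakpoint` if the best two-segment fit does
#' not reduce the residual of the flat one-segment fit by at least
#' `min_fit_gain` (fractionally) — the gene is then reported as
#' single-isoform with PDUI 100 and no breakpoint.
#'
#' @param x either a numeric matrix (positions x samples, transcript
#'   orientation, RPM units) or a list of normalized `coverage_track`
#'   objects for one gene.
#' @param sample_info optional data.frame with `sample_id`, `condition`,
#'   `replicate` matching the columns of `x` (taken from the tracks when
#'   `x` is a track list).
#' @param search_min guard (nt) from either UTR end for the breakpoint
#'   search.
#' @param min_mean_depth minimum mean depth (RPM) in at least one sample.
#' @param min_fit_gain minimum fractional residual reduction of the
#'   two-segment over the one-segment fit.
#' @param gene_id gene identifier (taken from tracks when available).
#' @return A `pdui_fit` object: list with `gene_id`, `breakpoint` (nt offset
#'   from the UTR 5' end, NA if none), `qc_flag`, `residual_ss`,
#'   `residual_ss_flat`, and `samples` (data.frame: `sample_id`,
#'   `condition`, `replicate`, `w_long`, `w_short`, `pdui`).
#' @examples
#' d <- c(rep(100, 300), rep(40, 700))        # step at 300, PDUI 40
#' fit <- fit_two_segment(matrix(d, ncol = 1), gene_id = "g")
#' fit$breakpoint; fit$samples$pdui
#' @export
fit_two_segment <- function(x, sample_info = NULL, search_min = 100L,
                            min_mean_depth = 1, min_fit_gain = 0.05,
                            gene_id = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    stopifnot(all(vapply(x, inherits, logical(1), "coverage_track")))
    stop_if(!all(vapply(x, `[[`, logical(1), "normalized")),
            "all tracks must be normalized before fitting")
    gids <- unique(vapply(x, `[[`, character(1), "gene_id"))
    stop_if(length(gids) != 1, "tracks cover different genes")
    gene_id <- gene_id %||% gids
    lens <- vapply(x, function(t) length(t$depth), integer(1))
    stop_if(length(unique(lens)) != 1, "tracks have unequal lengths")
    sample_info <- data.frame(
      sample_id = vapply(x, `[[`, character(1), "sample_id"),
      condition = vapply(x, `[[`, character(1), "condition"),
      replicate = vapply(x, `[[`, integer(1), "replicate"),
      stringsAsFactors = FALSE)
    x <- vapply(x, `[[`, numeric(lens[1]), "depth")
  }
  x <- as.matrix(x)
  L <- nrow(x)
  S <- ncol(x)
  stop_if(L < 2 * search_min,
          "UTR shorter than twice search_min (", L, " < ", 2 * search_min, ")")
  if (is.null(sample_info)) {
    sample_info <- data.frame(
      sample_id = colnames(x) %||% paste0("s", seq_len(S)),
      condition = NA_character_, replicate = NA_integer_,
      stringsAsFactors = FALSE)
  }
  gene_id <- gene_id %||% NA_character_

  col_mean <- colMeans(x)
  samples_df <- function(w_long, w_short) {
    tot <- w_long + w_short
    data.frame(sample_info,
               w_long = w_long, w_short = w_short,
               pdui = ifelse(tot > 0, 100 * w_long / tot, NA_real_),
               stringsAsFactors = FALSE)
  }
  if (!any(col_mean >= min_mean_depth)) {
    return(structure(list(gene_id = gene_id, breakpoint = NA_integer_,
                          qc_flag = "low_coverage",
                          residual_ss = NA_real_, residual_ss_flat = NA_real_,
                          samples = samples_df(rep(NA_real_, S),
                                               rep(NA_real_, S))),
                     class = "pdui_fit"))
  }

  B <- seq.int(search_min, L - search_min)
  css <- colSums(x^2)
  rss_flat <- css - L * col_mean^2
  rss_tot <- numeric(length(B))
  for (s in seq_len(S)) {
    cs <- cumsum(x[, s])
    m1 <- cs[B] / B
    m2 <- (cs[L] - cs[B]) / (L - B)
    rss <- css[s] - B * m1^2 - (L - B) * m2^2
    rss[m1 < m2] <- rss_flat[s]      # short-isoform weight clamped at zero
    rss_tot <- rss_tot + rss
  }
  best_rss <- min(rss_tot)
  b <- B[max(which(rss_tot == best_rss))]   # most distal among ties
  flat_tot <- sum(rss_flat)

  eps <- 1e-9 * max(1, sum(css))
  gain <- if (flat_tot > eps) (flat_tot - best_rss) / flat_tot else 0
  if (gain < min_fit_gain) {
    # no detectable proximal site: single full-length isoform
    return(structure(list(gene_id = gene_id, breakpoint = NA_integer_,
                          qc_flag = "no_breakpoint",
                          residual_ss = flat_tot,
                          residual_ss_flat = flat_tot,
                          samples = samples_df(col_mean, rep(0, S))),
                     class = "pdui_fit"))
  }

  w_long <- numeric(S)
  w_short <- numeric(S)
  for (s in seq_len(S)) {
    m1 <- mean(x[seq_len(b), s])
    m2 <- mean(x[(b + 1):L, s])
    if (m1 >= m2) {
      w_long[s] <- m2
      w_short[s] <- m1 - m2
    } else {
      w_long[s] <- col_mean[s]
      w_short[s] <- 0
    }
  }
  structure(list(gene_id = gene_id, breakpoint = as.integer(b),
                 qc_flag = "ok", residual_ss = best_rss,
                 residual_ss_flat = flat_tot,
                 samples = samples_df(w_long, w_short)),
            class = "pdui_fit")
}

#' @export
print.pdui_fit <- function(x, ...) {
  cat(sprintf("pdui_fit %s: breakpoint %s (%s), mean PDUI %.1f\n",
              x$gene_id,
              ifelse(is.na(x$breakpoint), "none", x$breakpoint),
              x$qc_flag, mean(x$samples$pdui, na.rm = TRUE)))
  invisible(x)
}

#' Fit the two-segment model for every gene of a coverage set
#'
#' @param cov a normalized `apa_coverage` object.
#' @param ... passed to [fit_two_segment()].
#' @return Named list of `pdui_fit` objects.
#' @export
fit_all_genes <- function(cov, ...) {
  stopifnot(inherits(cov, "apa_coverage"), isTRUE(cov$normalized))
  info <- cov$samples[, c("sample_id", "condition", "replicate")]
  fits <- lapply(names(cov$depth), function(gid)
    fit_two_segment(cov$depth[[gid]], sample_info = info, gene_id = gid, ...))
  names(fits) <- names(cov$depth)
  fits
}

#' Flatten fits into the per-sample fit table
#'
#' @param fits list of `pdui_fit` objects.
#' @return data.frame `gene_id breakpoint qc_flag sample_id condition
#'   replicate w_long w_short pdui`.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(gene_id = f$gene_id, breakpoint = f$breakpoint,
               qc_flag = f$qc_flag, f$samples,
               row.names = NULL, stringsAsFactors = FALSE)))
}

#' Test one gene's PDUI difference between two conditions
#'
#' Computes `dpdui = mean(PDUI_stim) - mean(PDUI_ref)` and a raw p-value.
#' The default test is Fisher's exact test on the 2x2 table of pooled
#' (summed, rounded) long/short isoform abundances per group, which stays
#' well behaved at three replicates per condition; a Welch t-test on the
#' per-replicate PDUI values is available as an alternative. With fewer
#' than two informative samples in either group the dPDUI is still reported
#' but `p_raw` is set to 1.
#'
#' @param fit a `pdui_fit` object.
#' @param ref,stim condition labels (reference / stimulated).
#' @param method `"fisher"` (pooled-abundance exact test) or `"t"` (Welch
#'   on per-replicate PDUI).
#' @return One-row data.frame: `gene_id`, `comparison`, `mean_pdui_ref`,
#'   `mean_pdui_stim`, `dpdui`, `p_raw`, `method`.
#' @export
test_event <- function(fit, ref, stim, method = c("fisher", "t")) {
  stopifnot(inherits(fit, "pdui_fit"))
  method <- match.arg(method)
  s <- fit$samples
  stop_if(!any(s$condition == ref, na.rm = TRUE), "empty reference group: ", ref)
  stop_if(!any(s$condition == stim, na.rm = TRUE), "empty stimulated group: ", stim)
  gr_ref <- s[s$condition %in% ref & !is.na(s$pdui), , drop = FALSE]
  gr_stim <- s[s$condition %in% stim & !is.na(s$pdui), , drop = FALSE]
  mean_ref <- if (nrow(gr_ref)) mean(gr_ref$pdui) else NA_real_
  mean_stim <- if (nrow(gr_stim)) mean(gr_stim$pdui) else NA_real_
  dpdui <- mean_stim - mean_ref

  p <- 1
  if (nrow(gr_ref) >= 2 && nrow(gr_stim) >= 2) {
    if (method == "fisher") {
      tab <- rbind(round(c(sum(gr_ref$w_long), sum(gr_ref$w_short))),
                   round(c(sum(gr_stim$w_long), sum(gr_stim$w_short))))
      if (all(rowSums(tab) > 0)) {
        p <- fisher.test(tab)$p.value
      }
    } else {
      p <- tryCatch(t.test(gr_stim$pdui, gr_ref$pdui)$p.value,
                    error = function(e) 1)
      if (is.na(p)) p <- 1
    }
  }
  data.frame(gene_id = fit$gene_id,
             comparison = paste(stim, "vs", ref),
             mean_pdui_ref = mean_ref, mean_pdui_stim = mean_stim,
             dpdui = dpdui, p_raw = p, method = method,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the event table for one pairwise comparison
#'
#' Runs [test_event()] over all fits. Genes flagged `low_coverage` are
#' skipped (not assessable); `no_breakpoint` genes are kept — their PDUI is
#' 100 in every sample, so they contribute null events and to the
#' assessable background.
#'
#' @param fits named list of `pdui_fit` objects.
#' @param ref,stim condition labels.
#' @param method see [test_event()].
#' @return data.frame, one row per assessable gene.
#' @export
call_apa_events <- function(fits, ref, stim, method = c("fisher", "t")) {
  method <- match.arg(method)
  keep <- vapply(fits, function(f) f$qc_flag != "low_coverage", logical(1))
  ev <- do.call(rbind, lapply(fits[keep], test_event,
                              ref = ref, stim = stim, method = method))
  rownames(ev) <- NULL
  ev
}

#' Adjust p-values and call event categories
#'
#' Applies Benjamini-Hochberg adjustment across the batch, then labels each
#' event: `shortened` when `dpdui <= -dpdui_threshold` with adjusted
#' p < `alpha`; `lengthened` symmetrically; `non_changing` when
#' `|dpdui| < nonchange_band` with raw p > `alpha`; everything else (and
#' events with missing values) is `indeterminate`.
#'
#' @param events data.frame with `dpdui` and `p_raw` (one comparison batch).
#' @param dpdui_threshold minimum |dPDUI| (percentage points) for a
#'   significant shift.
#' @param alpha significance level for the adjusted (and, for the
#'   non-changing rule, raw) p-value.
#' @param nonchange_band maximum |dPDUI| of a non-changing event.
#' @return The events data.frame with `p_adj` and `call` columns.
#' @export
adjust_and_call <- function(events, dpdui_threshold = 20, alpha = 0.05,
                            nonchange_band = 3) {
  stopifnot(is.data.frame(events), all(c("dpdui", "p_raw") %in% names(events)))
  events$p_adj <- p.adjust(events$p_raw, method = "BH")
  call <- rep("indeterminate", nrow(events))
  ok <- !is.na(events$dpdui) & !is.na(events$p_adj)
  call[ok & events$dpdui <= -dpdui_threshold & events$p_adj < alpha] <- "shortened"
  call[ok & events$dpdui >= dpdui_threshold & events$p_adj < alpha] <- "lengthened"
  nc <- ok & abs(events$dpdui) < nonchange_band & events$p_raw > alpha
  call[nc & !call %in% c("shortened", "lengthened")] <- "non_changing"
  events$call <- call
  events
}
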