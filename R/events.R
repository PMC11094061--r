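# Direction, basal-state, temporal and CD28-costimulation classification of
# called APA events, plus cross-condition correlation.

#' Count significant shortening vs lengthening events
#'
#' @param events a called event data.frame (see [adjust_and_call()]).
#' @return Named integer vector `c(shortened = , lengthened = )`, counting
#'   significant events only.
#' @export
direction_summary <- function(events) {
  stopifnot("call" %in% names(events))
  c(shortened = sum(events$call == "shortened"),
    lengthened = sum(events$call == "lengthened"))
}

#' Bin basal (unstimulated) PDUI into short / mid / long classes
#'
#' Tertile convention: `long` above 66, `short` below 33, `mid` otherwise
#' (both cuts exclusive, so a PDUI of exactly 66 is `mid`).
#'
#' @param basal_pdui numeric vector in \[0, 100\].
#' @param short_cut,long_cut bin boundaries.
#' @return Factor with levels `short`, `mid`, `long`.
#' @export
basal_pdui_bin <- function(basal_pdui, short_cut = 33, long_cut = 66) {
  stop_if(any(basal_pdui < 0 | basal_pdui > 100, na.rm = TRUE),
          "basal PDUI must lie in [0, 100]")
  out <- ifelse(basal_pdui > long_cut, "long",
                ifelse(basal_pdui < short_cut, "short", "mid"))
  factor(out, levels = c("short", "mid", "long"))
}

#' Classify events by time point
#'
#' A gene is `48h_only` when it is significant (shortened or lengthened) at
#' 48 h while called non-changing at 8 h; `8h_only` symmetrically; `both`
#' when significant at both time points; `other` for every remaining
#' combination (an indeterminate call at the other time point is not
#' evidence of non-change, so such genes fall into `other`).
#'
#' @param call_8h,call_48h aligned character vectors of event calls for the
#'   same genes under the same stimulus at 8 h and 48 h.
#' @return Factor with levels `8h_only`, `48h_only`, `both`, `other`;
#'   every gene receives exactly one label.
#' @export
temporal_classify <- function(call_8h, call_48h) {
  stop_if(length(call_8h) != length(call_48h),
          "call vectors must be aligned (same genes, same order)")
  sig <- c("shortened", "lengthened")
  s8 <- call_8h %in% sig
  s48 <- call_48h %in% sig
  out <- rep("other", length(call_8h))
  out[s8 & s48] <- "both"
  out[s8 & call_48h == "non_changing"] <- "8h_only"
  out[s48 & call_8h == "non_changing"] <- "48h_only"
  factor(out, levels = c("8h_only", "48h_only", "both", "other"))
}

#' CD28 costimulation enhancement ratio
#'
#' Ratio of APA change magnitudes under CD3/CD28 costimulation versus CD3
#' alone: `|dpdui_cd3cd28| / max(|dpdui_cd3|, floor)`. Very small CD3
#' denominators are floored (default 1 percentage point) to prevent
#' misleading skewing of the ratio. An event is flagged `enhanced` when the
#' ratio exceeds `threshold` (default 2-fold). Sign-discordant pairs
#' (shortening under one stimulus, lengthening under the other) are flagged
#' separately rather than folded into the ratio; the ratio itself uses
#' absolute values and is invariant to a simultaneous sign flip of both
#' inputs.
#'
#' @param dpdui_cd3cd28,dpdui_cd3 paired dPDUI vectors (percentage points).
#' @param floor minimum denominator magnitude.
#' @param threshold fold-change above which an event counts as enhanced.
#' @return data.frame with `ratio`, `enhanced`, `discordant`.
#' @export
cd28_ratio <- function(dpdui_cd3cd28, dpdui_cd3, floor = 1, threshold = 2) {
  stop_if(length(dpdui_cd3cd28) != length(dpdui_cd3),
          "dPDUI vectors must be paired")
  ratio <- abs(dpdui_cd3cd28) / pmax(abs(dpdui_cd3), floor)
  discordant <- sign(dpdui_cd3cd28) * sign(dpdui_cd3) < 0
  data.frame(ratio = ratio,
             enhanced = ratio > threshold,
             discordant = discordant)
}

#' Pearson correlation and OLS regression of paired dPDUI vectors
#'
#' @param x,y paired numeric vectors (length >= 3 after removing
#'   incomplete pairs).
#' @return List with `r` (Pearson), `slope`, `intercept`, `n`.
#' @export
condition_correlation <- function(x, y) {
  stop_if(length(x) != length(y), "vectors must be paired")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  stop_if(length(x) < 3, "need at least 3 complete pairs")
  fit <- lm(y ~ x)
  list(r = cor(x, y),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       n = length(x))
}

#' Assemble the per-gene comparison table
#'
#' Joins event tables from several pairwise comparisons into one wide table
#' keyed by gene, with the dPDUI and call of each comparison and the basal
#' (reference-condition) mean PDUI.
#'
#' @param event_list named list of called event data.frames; names label
#'   the comparisons.
#' @return data.frame with `gene_id`, `basal_pdui`, and per comparison
#'   `dpdui_<name>` / `call_<name>` columns.
#' @export
event_comparison_table <- function(event_list) {
  stop_if(is.null(names(event_list)) || any(names(event_list) == ""),
          "event_list must be named by comparison")
  out <- NULL
  for (nm in names(event_list)) {
    ev <- event_list[[nm]]
    d <- ev[, c("gene_id", "mean_pdui_ref", "dpdui", "call")]
    names(d) <- c("gene_id", "basal_pdui",
                  paste0("dpdui_", nm), paste0("call_", nm))
    out <- if (is.null(out)) d else
      merge(out, d[, -2], by = "gene_id", all = TRUE)
  }
  out
}
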