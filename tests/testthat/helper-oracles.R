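# Independent brute-force oracles and small fixture builders used across the
# test suite. Each oracle recomputes a quantity by the most direct method
# available (naive sums, per-offset rescans, log-space enumeration) without
# sharing code with the implementation it checks.

# Exhaustive two-segment minimizer: loops over every candidate breakpoint,
# solves the clamped non-negative fit per sample by direct segment means,
# and accumulates the residual by direct summation. Ties broken toward the
# most distal candidate.
oracle_fit_two_segment <- function(mat, search_min = 100) {
  L <- nrow(mat)
  best_b <- NA_integer_
  best_rss <- Inf
  for (b in seq(search_min, L - search_min)) {
    rss <- 0
    for (s in seq_len(ncol(mat))) {
      d <- mat[, s]
      up <- d[seq_len(b)]
      down <- d[(b + 1):L]
      if (mean(up) >= mean(down)) {
        rss <- rss + sum((up - mean(up))^2) + sum((down - mean(down))^2)
      } else {
        rss <- rss + sum((d - mean(d))^2)
      }
    }
    if (rss <= best_rss) {  # <= keeps the largest b among exact ties
      best_rss <- rss
      best_b <- b
    }
  }
  pdui <- vapply(seq_len(ncol(mat)), function(s) {
    d <- mat[, s]
    m1 <- mean(d[seq_len(best_b)])
    m2 <- mean(d[(best_b + 1):L])
    if (m1 < m2) { m2 <- mean(d); m1 <- m2 }
    w_long <- m2
    w_short <- m1 - m2
    if (w_long + w_short > 0) 100 * w_long / (w_long + w_short) else NA_real_
  }, numeric(1))
  list(breakpoint = best_b, rss = best_rss, pdui = pdui)
}

# Two-sided Fisher p for a 2x2 table by full enumeration of the
# hypergeometric support (sum of all outcomes at most as probable as the
# observed one, the classic two-sided rule).
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric p by explicit log-space enumeration.
oracle_hyper_upper <- function(overlap, set_n, background_n, query_n) {
  ks <- overlap:min(query_n, set_n)
  if (length(ks) == 0 || overlap > min(query_n, set_n)) return(0)
  terms <- lchoose(set_n, ks) + lchoose(background_n - set_n, query_n - ks) -
    lchoose(background_n, query_n)
  sum(exp(terms))
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Naive per-offset rescan of the sliding-window motif fraction: for each
# offset, extract the window substring of each event, enumerate every
# in-window start of the motif, and count the event if at least one
# occurrence remains after dropping occurrences whose leading k-mer (in the
# full sequence) equals the excluded hexamer.
oracle_motif_map <- function(windows, motif = "AAUAUA", exclude = "AAUAAA",
                             window_nt = 10, span = c(-100, 100)) {
  offsets <- seq(span[1], span[2])
  n <- nrow(windows)
  frac <- numeric(length(offsets))
  mlen <- nchar(motif)
  for (oi in seq_along(offsets)) {
    o <- offsets[oi]
    hit <- 0
    for (i in seq_len(n)) {
      s <- windows$sequence[i]
      lo <- windows$site_offset[i] + o + 1      # 1-based window start
      lo_c <- max(1, lo)
      hi_c <- min(nchar(s), lo + window_nt - 1)
      found <- FALSE
      if (hi_c - lo_c + 1 >= mlen) {
        for (j in lo_c:(hi_c - mlen + 1)) {
          if (substr(s, j, j + mlen - 1) == motif &&
              (!nzchar(exclude) ||
                 substr(s, j, j + nchar(exclude) - 1) != exclude)) {
            found <- TRUE
            break
          }
        }
      }
      if (found) hit <- hit + 1
    }
    frac[oi] <- if (n > 0) hit / n else NA_real_
  }
  data.frame(offset = offsets, raw_fraction = frac)
}

# Tiny deterministic single-gene coverage matrix builders.
step_matrix <- function(high, low, offset, L, n_samples = 1) {
  matrix(rep(c(rep(high, offset), rep(low, L - offset)), n_samples),
         ncol = n_samples)
}
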