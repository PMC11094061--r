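# Helper: build a pas_windows row directly from an RNA string.
window_df <- function(sequence, site_offset, gene_id = "g",
                      site_kind = "dPAS") {
  out <- data.frame(gene_id = gene_id, site_kind = site_kind,
                    sequence = sequence, site_offset = site_offset,
                    truncated = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("pas_windows", "data.frame")
  out
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

test_that("extract_pas_windows slices transcript-oriented windows", {
  seqs <- c(g1 = paste0(strrep("C", 300), "AATAAA", strrep("G", 94),
                        strrep("T", 100)))
  # site at offset 400 (0-based); AATAAA occupies offsets 300..305
  sites <- data.frame(gene_id = "g1", site = 400L, site_kind = "pPAS")
  w <- extract_pas_windows(sites, seqs, flank_up = 200, flank_down = 100)
  expect_equal(w$site_offset, 200)
  expect_equal(nchar(w$sequence), 300)
  expect_false(w$truncated)
  # planted hexamer sits 100 nt upstream of the site, transliterated to RNA
  expect_equal(substr(w$sequence, 101, 106), "AAUAAA")
  expect_equal(substr(w$sequence, 201, 201), "U")  # first downstream base

  # windows running past the sequence end are truncated and flagged
  sites2 <- data.frame(gene_id = "g1", site = 450L, site_kind = "dPAS")
  expect_warning(w2 <- extract_pas_windows(sites2, seqs), "truncated")
  expect_true(w2$truncated)
  expect_equal(nchar(w2$sequence), 250)
})

test_that("pas_signal_presence enforces the 100-nt upstream rule", {
  # AAUAAA starting 20 nt upstream of the site
  w <- window_df(paste0(strrep("C", 180), "AAUAAA", strrep("C", 14),
                        strrep("G", 50)), 200)
  p <- pas_signal_presence(w)
  expect_true(p$has_AAUAAA)
  expect_false(p$has_UGUA)

  # AAUAAA 150 nt upstream only: outside the 100-nt rule
  w <- window_df(paste0(strrep("C", 50), "AAUAAA", strrep("C", 144),
                        strrep("G", 50)), 200)
  expect_false(pas_signal_presence(w)$has_AAUAAA)

  # UGUA at -50, no core hexamer
  w <- window_df(paste0(strrep("C", 150), "UGUA", strrep("C", 46),
                        strrep("G", 50)), 200)
  p <- pas_signal_presence(w)
  expect_false(p$has_AAUAAA)
  expect_true(p$has_UGUA)
})

test_that("pas_strength_summary reports per-site-kind fractions", {
  seq_with <- paste0(strrep("C", 150), "AAUAAA", strrep("C", 44), "G")
  seq_without <- paste0(strrep("C", 200), "G")
  w <- rbind(window_df(seq_with, 200, "g1", "pPAS"),
             window_df(seq_without, 200, "g2", "pPAS"),
             window_df(seq_with, 200, "g1", "dPAS"),
             window_df(seq_with, 200, "g2", "dPAS"))
  s <- pas_strength_summary(w)
  expect_equal(s$frac_AAUAAA[s$site_kind == "pPAS"], 0.5)
  expect_equal(s$frac_AAUAAA[s$site_kind == "dPAS"], 1.0)
  expect_equal(s$n, c(2L, 2L))

  # empty filter: zero counts, no error
  s0 <- pas_strength_summary(w, event_filter = character(0))
  expect_equal(s0$n, c(0L, 0L))
  expect_true(all(is.na(s0$frac_AAUAAA)))
})

test_that("motif map single-event geometry and exclusion rule", {
  # one event, AAUAUA starting exactly at the site: windows [o, o+10)
  # containing positions 0..5 are exactly o in -4..0
  w <- window_df(paste0(strrep("C", 150), "AAUAUA", strrep("C", 94)), 150)
  prof <- motif_positional_map(w, span = c(-20, 20))
  expect_equal(prof$raw_fraction[prof$offset %in% -4:0], rep(1, 5))
  expect_equal(sum(prof$raw_fraction), 5)

  # windows containing only the core PAS hexamer score zero
  w2 <- window_df(paste0(strrep("C", 150), "AAUAAA", strrep("C", 94)), 150)
  expect_equal(sum(motif_positional_map(w2, span = c(-20, 20))$raw_fraction), 0)

  # a degenerate pattern matching the core hexamer is excluded at those hits
  w3 <- window_df(paste0(strrep("C", 150), "AAUAAA", strrep("C", 94)), 150)
  prof3 <- motif_positional_map(w3, motif = "AAUAAA", exclude = "AAUAAA",
                                span = c(-20, 20))
  expect_equal(sum(prof3$raw_fraction), 0)
  prof4 <- motif_positional_map(w3, motif = "AAUAAA", exclude = "",
                                span = c(-20, 20))
  expect_equal(sum(prof4$raw_fraction), 5)
})

test_that("motif map equals the brute-force per-offset rescan exactly", {
  set.seed(59)
  rows <- lapply(1:50, function(i) {
    s <- rand_rna(320)
    # plant some AAUAUA / AAUAAA occurrences at random positions
    if (runif(1) < 0.7) {
      at <- sample(1:315, 1)
      substr(s, at, at + 5) <- sample(c("AAUAUA", "AAUAAA"), 1)
    }
    window_df(s, sample(150:220, 1), gene_id = paste0("g", i))
  })
  w <- do.call(rbind, rows)
  prof <- motif_positional_map(w, span = c(-100, 100))
  oracle <- oracle_motif_map(w, span = c(-100, 100))
  expect_identical(prof$raw_fraction, oracle$raw_fraction)
  expect_equal(attr(prof, "n_events"), 50)

  # event-order invariance
  prof_rev <- motif_positional_map(w[rev(seq_len(nrow(w))), ],
                                   span = c(-100, 100))
  expect_identical(prof$raw_fraction, prof_rev$raw_fraction)
})

test_that("smoothing is a shrinking-edge running mean that conserves mass", {
  w <- do.call(rbind, lapply(1:10, function(i) {
    set.seed(60 + i)
    window_df(rand_rna(320), 160, gene_id = paste0("g", i))
  }))
  prof <- motif_positional_map(w, span = c(-50, 50))
  raw <- prof$raw_fraction
  n <- length(raw)
  sm_hand <- vapply(seq_len(n), function(i)
    mean(raw[max(1, i - 2):min(n, i + 2)]), numeric(1))
  expect_equal(prof$smoothed_fraction, sm_hand)
  # interior mass conservation (edges use shrinking windows)
  expect_equal(mean(prof$smoothed_fraction[3:(n - 2)]),
               mean(vapply(3:(n - 2), function(i) mean(raw[(i - 2):(i + 2)]),
                           numeric(1))))
})

test_that("compare_profiles handles groups, duplicates and empties", {
  w <- rbind(window_df(paste0(strrep("C", 150), "AAUAUA", strrep("C", 94)),
                       150, "g1"),
             window_df(paste0(strrep("C", 150), "AAUAUA", strrep("C", 94)),
                       150, "g2"))
  out <- compare_profiles(w, list(a = c("g1", "g2"), b = c("g1", "g2"),
                                  empty = character(0)),
                          span = c(-10, 10))
  a <- out[out$group == "a", ]
  b <- out[out$group == "b", ]
  expect_equal(a$raw_fraction, b$raw_fraction)  # identical windows
  e <- out[out$group == "empty", ]
  expect_true(all(e$n_events == 0))
  expect_true(all(is.na(e$raw_fraction)))
})

test_that("pas_sites derives proximal/distal sites with optional override", {
  fits <- data.frame(gene_id = c("g1", "g2"), breakpoint = c(250L, NA))
  lens <- c(g1 = 900L, g2 = 700L)
  s <- pas_sites(fits, lens)
  expect_equal(s$site[s$gene_id == "g1" & s$site_kind == "pPAS"], 250)
  expect_equal(s$site[s$gene_id == "g1" & s$site_kind == "dPAS"], 900)
  expect_false("g2" %in% s$gene_id)    # no breakpoint, no sites

  s2 <- pas_sites(fits, lens, override = data.frame(gene_id = "g2",
                                                    breakpoint = 300L))
  expect_equal(s2$site[s2$gene_id == "g2" & s2$site_kind == "pPAS"], 300)
})
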