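# Window extraction (strand-aware), alternative-site geometry and the
# 3-nt periodicity summary.

test_that("plus-strand donor windows read exon|intron across the boundary", {
  g <- toy_genome_with_donor()   # CAG|GTAAGT stamped at boundary 100 on chrF
  ev <- make_events("g1;A5:chrF:100-220:112-220:+", "g1", "A5", "chrF", "+",
                    list(c(100L, 112L, 220L)),
                    list("t1"), list(c("t1", "t2")))
  w <- extract_site_windows(ev, g)
  don <- w[w$role == "original" & w$site_kind == "donor", ]
  expect_identical(don$sequence, "CAGGTAAGT")
})

test_that("minus-strand windows equal the reverse-complement oracle", {
  g <- toy_genome_with_donor()
  L <- length(g[["chrR"]])
  # the same locus on the reverse-complemented contig: boundary maps to
  # L + 1 - 100 and the window string must be identical
  ev <- make_events("g1;A5:chrR:201-81:189-81:-", "g1", "A5", "chrR", "-",
                    list(c(L + 1L - 100L, L + 1L - 112L, 81L)),
                    list("t1"), list(c("t1", "t2")))
  w <- extract_site_windows(ev, g)
  don <- w[w$role == "original" & w$site_kind == "donor", ]
  expect_identical(don$sequence, "CAGGTAAGT")
})

test_that("strand involution: flipping the locus leaves window strings fixed", {
  sim <- small_sim()
  w <- extract_site_windows(sim$events, sim$genome)
  # rebuild the genome with every contig reverse-complemented and flip
  # strands and boundary coordinates accordingly
  g2 <- Biostrings::reverseComplement(sim$genome)
  ev <- sim$events
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  ev$strand <- ifelse(ev$strand == "+", "-", "+")
  ev$coords <- lapply(seq_len(nrow(ev)), function(i)
    as.integer(lens[[ev$contig[i]]] + 1L - ev$coords[[i]]))
  ev$event_id <- vapply(seq_len(nrow(ev)), function(i)
    format_event_id(ev$gene_id[i], ev$event_class[i], ev$contig[i],
                    ev$strand[i], ev$coords[[i]]), "")
  w2 <- extract_site_windows(splice_events(ev), g2)
  expect_identical(w2$sequence, w$sequence)
})

test_that("windows containing N are flagged", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 97), "CAGGTNAGT", strrep("A", 60))))
  ev <- make_events("g1;A5:chr1:100-160:115-160:+", "g1", "A5", "chr1", "+",
                    list(c(100L, 115L, 160L)),
                    list("t1"), list(c("t1", "t2")))
  w <- extract_site_windows(ev, g)
  expect_true(w$contains_N[w$role == "original"])
  # and N-flagged windows are excluded from PFMs
  pm <- build_pfm(w[w$site_kind == "donor", ])
  expect_identical(pm$n_sequences, 1L)
})

test_that("out-of-bounds windows are dropped with a warning", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 30)))
  ev <- make_events("g1;A5:chr1:2-100:20-100:+", "g1", "A5", "chr1", "+",
                    list(c(2L, 20L, 100L)),
                    list("t1"), list(c("t1", "t2")))
  expect_warning(w <- extract_site_windows(ev, g), "dropped")
  expect_false(any(w$boundary == 2L & w$site_kind == "donor"))
  expect_true(any(w$boundary == 20L & w$site_kind == "donor"))
})

test_that("SE events also emit flanking donor/acceptor windows", {
  sim <- small_sim()
  w <- extract_site_windows(sim$events, sim$genome)
  se <- w[w$event_class == "SE", ]
  per_event <- table(se$event_id, se$role)
  expect_true(all(per_event[, "upstream-flank"] == 1))
  expect_true(all(per_event[, "downstream-flank"] == 1))
  expect_true(all(per_event[, "canonical"] == 2))
  ri <- w[w$event_class == "RI", ]
  expect_true(all(table(ri$event_id, ri$site_kind) == 1))
})

test_that("site distance is signed in transcript orientation", {
  evp <- make_events("g1;A5:chr1:1000-1200:1010-1200:+", "g1", "A5",
                     "chr1", "+", list(c(1000L, 1010L, 1200L)),
                     list("t1"), list(c("t1", "t2")))
  gp <- site_distance(evp)
  expect_identical(gp$distance, 10L)
  expect_identical(gp$direction, "downstream")
  # same genomic layout on the minus strand: alternative is upstream
  evm <- make_events("g1;A5:chr1:1000-900:1010-900:-", "g1", "A5",
                     "chr1", "-", list(c(1000L, 1010L, 900L)),
                     list("t1"), list(c("t1", "t2")))
  gm <- site_distance(evm)
  expect_identical(gm$distance, -10L)
  expect_identical(gm$direction, "upstream")
  # -6 falls in periodicity class 0
  ev6 <- make_events("g1;A3:chr1:106-50:100-50:+", "g1", "A3",
                     "chr1", "+", list(c(106L, 100L, 50L)),
                     list("t1"), list(c("t1", "t2")))
  g6 <- site_distance(ev6)
  expect_identical(g6$distance, -6L)
  expect_identical(g6$periodicity_class, 0L)
})

test_that("the control-dominant variant is taken as original", {
  ev <- make_events("g1;A5:chr1:100-300:110-300:+", "g1", "A5", "chr1", "+",
                    list(c(100L, 110L, 300L)),
                    list("t1"), list(c("t1", "t2")))
  design <- data.frame(sample_id = c("w1", "w2", "m1", "m2"),
                       condition = c("wildtype", "wildtype",
                                     "mutant", "mutant"))
  psi_hi <- matrix(c(0.8, 0.9, 0.5, 0.5), 1,
                   dimnames = list(ev$event_id, design$sample_id))
  expect_identical(site_distance(ev, psi_hi, design)$original_variant, 1L)
  psi_lo <- psi_hi; psi_lo[1, 1:2] <- c(0.2, 0.1)
  g <- site_distance(ev, psi_lo, design)
  expect_identical(g$original_variant, 2L)
  # antisymmetry under swapping the original/alternative assignment
  expect_identical(g$distance,
                   -site_distance(ev, psi_hi, design)$distance)
  # ties fall back to variant 1 with a message
  psi_tie <- psi_hi; psi_tie[1, 1:2] <- 0.5
  expect_message(gt <- site_distance(ev, psi_tie, design), "variant 1")
  expect_identical(gt$original_variant, 1L)
})

test_that("periodicity summary counts residue classes and tests uniformity", {
  gm <- data.frame(distance = c(3, 6, -3, 9, 3, -6),
                   periodicity_class = c(3, 6, -3, 9, 3, -6) %% 3)
  s <- periodicity_summary(gm)
  expect_equal(unname(s$residue_counts), c(6, 0, 0))
  expect_equal(unname(s$fraction_in_frame), 1)
  # uniform residues -> statistic 0
  gu <- data.frame(distance = 1:30, periodicity_class = rep(0:2, 10))
  expect_equal(periodicity_summary(gu)$chisq$statistic, 0)
  # counts (20, 5, 5) -> chi-square 15 with df 2
  gc <- data.frame(distance = 1:30,
                   periodicity_class = rep(c(0, 1, 2), c(20, 5, 5)))
  s3 <- periodicity_summary(gc)
  expect_equal(s3$chisq$statistic, 15)
  expect_equal(s3$chisq$p_value, pchisq(15, 2, lower.tail = FALSE))
})

test_that("simulated A5/A3 shifts are biased to multiples of 3", {
  sim <- small_sim()
  psi <- compute_psi(sim$events, sim$tpm)
  g <- suppressMessages(site_distance(sim$events, psi, sim$design))
  s <- periodicity_summary(g)
  expect_gt(s$fraction_in_frame, 0.5)
  expect_true(all(abs(g$distance) >= 10))
})
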