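# Position matrices, information content, G-tests, U5/U6 classes,
# strength scoring and shift categories.

test_that("PFM/PPM columns are consistent and IC has its closed-form values", {
  pm <- build_pfm(c("AAGT", "ACGT", "AGGT", "ATGT"))
  expect_true(all(colSums(pm$pfm) == 4))
  expect_equal(unname(colSums(pm$ppm)), rep(1, 4), tolerance = 1e-9)
  # uniform column -> 0 bits; all-same -> 2 bits
  expect_equal(unname(pm$ic), c(2, 0, 2, 2), tolerance = 1e-12)
  # two equiprobable bases -> 1 bit
  pm2 <- build_pfm(c("A", "G"))
  expect_equal(unname(pm2$ic), 1, tolerance = 1e-12)
  expect_true(all(pm$ic >= 0 & pm$ic <= 2))
  expect_error(build_pfm(c("AA", "AAA")), "mixed widths")
})

test_that("G-test matches direct formula evaluation and is symmetric", {
  # derived case: 2x2 table [[30,10],[10,30]], E = 20 everywhere
  g <- gtest_table(matrix(c(30, 10, 10, 30), 2))
  expect_equal(g$statistic, 2 * (60 * log(1.5) + 20 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(g$statistic, 20.93, tolerance = 1e-2)
  expect_equal(g$df, 1L)
  # identical count columns -> G = 0, p = 1
  a <- build_pfm(c("ACGT", "AGGT", "ATGT"))
  same <- gtest_motif(a, a)
  expect_equal(same$per_position$G, rep(0, 4), tolerance = 1e-12)
  expect_equal(same$overall$p_value, 1)
  # symmetry in the two arguments
  b <- build_pfm(c("TCGA", "ACGA", "ACTT"))
  expect_equal(gtest_motif(a, b)$overall$statistic,
               gtest_motif(b, a)$overall$statistic, tolerance = 1e-12)
  # brute-force oracle on random tables: G = 2 sum O log(O/E)
  set.seed(31)
  for (i in 1:100) {
    tab <- matrix(rpois(8, 12), 2)
    res <- gtest_table(tab)
    keep <- colSums(tab) > 0
    tab2 <- tab[, keep, drop = FALSE]
    E <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
    ora <- 2 * sum(tab2 * log(tab2 / E), na.rm = TRUE)
    if (!is.na(res$statistic)) {
      expect_equal(res$statistic, ora, tolerance = 1e-9)
      expect_gte(res$statistic, -1e-12)
    }
  }
})

test_that("bases absent from both sets reduce the degrees of freedom", {
  a <- build_pfm(c("A", "A", "G"))
  b <- build_pfm(c("A", "G", "G"))
  res <- gtest_motif(a, b)
  expect_equal(res$per_position$df, 1)   # only A and G present
})

test_that("U5/U6 classification follows the AG and RAG consensus rules", {
  win <- function(s) {
    d <- data.frame(site_kind = "donor", sequence = s, contains_N = FALSE,
                    stringsAsFactors = FALSE)
    attr(d, "widths") <- default_window_widths()
    d
  }
  # leading base is position -3; the tested positions are -2,-1 | +3,+4,+5
  cl <- classify_u5_u6(win(c("CAGGTAAGT", "ACCGTTTCT", "CAGGTGAGA",
                             "CAGGTCAGT")))
  expect_identical(cl$u5_state, c("consensus", "deviant", "consensus",
                                  "consensus"))
  expect_identical(cl$u6_state, c("consensus", "deviant", "consensus",
                                  "deviant"))
  expect_identical(cl$joint_class[2], "u5_deviant/u6_deviant")
  expect_error(classify_u5_u6(data.frame(site_kind = "acceptor",
                                         sequence = "AAAAAAAAAA")),
               "donor")
})

test_that("U5/U6 contingency table cross-tabulates two window sets", {
  sim <- small_sim()
  w <- extract_site_windows(sim$events, sim$genome)
  don <- w[w$site_kind == "donor", ]
  half <- seq_len(nrow(don)) %% 2 == 0
  res <- u5u6_contingency(don[half, ], don[!half, ])
  expect_identical(dim(res$table), c(4L, 2L))
  expect_identical(sum(res$table), nrow(don))
  expect_true(res$gtest$statistic >= 0)
  tab <- u5u6_crosstab(don, top_k = 4)
  expect_lte(nrow(tab), 4L)
  expect_lte(ncol(tab), 4L)
})

test_that("strength scores behave as log-odds against uniform background", {
  sim <- small_sim()
  bg <- annotated_site_windows(sim$annotation, sim$genome)
  don <- bg[bg$site_kind == "donor", ]
  model <- suppressMessages(build_strength_model(don))
  scored <- score_site_strength(don, model)
  # the per-position argmax sequence scores at least as high as any site
  ppm <- pmax(model$pfm$ppm, model$p_floor)
  best <- sum(log2(apply(ppm, 2, max) / 0.25))
  expect_true(all(scored$score <= best + 1e-9))
  # uniform background model -> every window scores 0
  unif <- model
  unif$pfm$ppm[] <- 0.25
  expect_equal(strength_scores(don, unif), rep(0, nrow(don)),
               tolerance = 1e-12)
  # median threshold labels about half of an odd-sized site set strong
  odd <- don[seq_len(nrow(don) - (1 - nrow(don) %% 2)), ]
  mmed <- suppressMessages(build_strength_model(odd,
                                                threshold_method = "median"))
  lab <- score_site_strength(odd, mmed)$label
  expect_equal(mean(lab == "strong"), 0.5, tolerance = 2 / nrow(odd))
  expect_error(score_site_strength(
    data.frame(site_kind = "donor", sequence = "ACGT"), model), "width")
})

test_that("strength labels recover the generated strong/weak truth", {
  sim <- recovery_sim()
  w <- extract_site_windows(sim$events, sim$genome)
  bg <- annotated_site_windows(sim$annotation, sim$genome)
  ts <- sim$truth$sites
  key <- function(d) paste(d$contig, d$boundary, d$site_kind)
  agree <- vapply(c("donor", "acceptor"), function(k) {
    model <- suppressMessages(build_strength_model(bg[bg$site_kind == k, ]))
    sw <- score_site_strength(w[w$site_kind == k, ], model)
    mean(sw$label == ts$strength[match(key(sw), key(ts))], na.rm = TRUE)
  }, numeric(1))
  expect_gte(min(agree), 0.95)
})

test_that("synthetic strong donors are all (consensus, consensus) in U5/U6", {
  sim <- simulate_genome_and_events(
    sim_config(n_genes = 30, strong_site_fraction = 1, seed = 8))
  w <- extract_site_windows(sim$events, sim$genome)
  cl <- classify_u5_u6(w[w$site_kind == "donor", ])
  expect_true(all(cl$joint_class == "u5_consensus/u6_consensus"))
  # weak sites deviate by construction
  simw <- simulate_genome_and_events(
    sim_config(n_genes = 30, strong_site_fraction = 0, seed = 8))
  ww <- extract_site_windows(simw$events, simw$genome)
  clw <- classify_u5_u6(ww[ww$site_kind == "donor", ])
  expect_lt(mean(clw$joint_class == "u5_consensus/u6_consensus"), 1)
})

test_that("shift categories read losing site to gaining site", {
  pairs <- data.frame(
    event_id = c("e1", "e2", "e3", "e4"),
    original_label = c("strong", "weak", "strong", "weak"),
    alternative_label = c("weak", "weak", "weak", "strong"),
    # negative delta: the alternative site gains usage in the mutant
    delta_psi = c(-0.3, -0.2, 0.25, -0.4),
    losing_site_mutant_psi = c(0.02, 0.3, 0.4, 0.2))
  res <- classify_shifts(pairs)
  expect_identical(res$pairs$shift,
                   c("strong->weak", "weak->weak", "weak->strong",
                     "weak->strong"))
  expect_identical(res$pairs$complete, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(res$counts["weak->strong"]), 2L)
  expect_error(classify_shifts(data.frame(event_id = "e1")), "columns")
})
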