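# Cross-dataset event matching, the Pearson chi-square overlap test and
# direction concordance.

fake_records <- function(keys, classes, q, d, p = q) {
  call_significant(data.frame(
    event_id = paste0("ev", seq_along(keys)),
    event_class = classes, event_key = keys,
    delta_psi = d, p_value = p, q_value = q,
    stringsAsFactors = FALSE))
}

test_that("events match on coordinates, not identifiers", {
  keys <- c("chr1:+:SE:100-200-300-400", "chr1:-:RI:10-20-80-90")
  a <- fake_records(keys, c("SE", "RI"), c(0.01, 0.5), c(0.3, 0.1))
  b <- fake_records(keys, c("SE", "RI"), c(0.2, 0.01), c(0.2, -0.2))
  b$event_id <- paste0("other", 1:2)   # different names, same coordinates
  u <- match_events(a, b)
  expect_identical(nrow(u), 2L)
  # identical files -> universe is all tested events
  expect_identical(nrow(match_events(a, a)), 2L)
  # disjoint coordinate spaces -> empty with a warning
  b2 <- b; b2$event_key <- c("chr9:+:SE:1-2-3-4", "chr9:-:RI:5-6-7-8")
  expect_warning(u0 <- match_events(a, b2), "no shared")
  expect_identical(nrow(u0), 0L)
  # untested (NA p) events drop out of the tested universe
  a3 <- a; a3$p_value[2] <- NA
  expect_identical(nrow(match_events(a3, b)), 1L)
  expect_identical(nrow(match_events(a3, b, universe = "all")), 2L)
})

test_that("overlap chi-square equals the 2x2 closed form", {
  # derived case [[30,10],[10,30]]: n(ad-bc)^2 / prod(margins) = 20
  n <- 80
  keys <- paste0("k", seq_len(n))
  sig_a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 10, 30))
  sig_b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  a <- fake_records(keys, "SE", ifelse(sig_a, 0.01, 0.5), 0.2)
  b <- fake_records(keys, "SE", ifelse(sig_b, 0.01, 0.5), 0.2)
  res <- chisq_overlap(match_events(a, b))
  expect_equal(res$chisq[res$event_class == "SE"],
               80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40),
               tolerance = 1e-9)
  expect_equal(res$chisq[res$event_class == "SE"], 20, tolerance = 1e-9)
  expect_identical(res$n_both[res$event_class == "SE"], 30L)
  # independence: balanced table -> statistic 0, p = 1
  sig_b0 <- rep(c(TRUE, FALSE), 40)
  b0 <- fake_records(keys, "SE", ifelse(sig_b0, 0.01, 0.5), 0.2)
  sig_a0 <- rep(c(TRUE, TRUE, FALSE, FALSE), 20)
  a0 <- fake_records(keys, "SE", ifelse(sig_a0, 0.01, 0.5), 0.2)
  res0 <- chisq_overlap(match_events(a0, b0))
  expect_equal(res0$chisq[res0$event_class == "SE"], 0, tolerance = 1e-12)
  expect_equal(res0$p_value[res0$event_class == "SE"], 1, tolerance = 1e-12)
})

test_that("chi-square matches the closed form on random tables", {
  pearson_oracle <- function(a, b, c_, d) {
    n <- a + b + c_ + d
    n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
  }
  set.seed(77)
  for (i in 1:100) {
    cells <- rpois(4, 15) + 1
    keys <- paste0("k", seq_len(sum(cells)))
    sa <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    sb <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    a <- fake_records(keys, "RI", ifelse(sa, 0.01, 0.5), 0.1)
    b <- fake_records(keys, "RI", ifelse(sb, 0.01, 0.5), 0.1)
    res <- chisq_overlap(match_events(a, b))
    expect_equal(res$chisq[res$event_class == "RI"],
                 pearson_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("swapping the datasets leaves the statistic unchanged", {
  set.seed(3)
  keys <- paste0("k", 1:60)
  a <- fake_records(keys, "SE", runif(60), runif(60, -1, 1))
  b <- fake_records(keys, "SE", runif(60), runif(60, -1, 1))
  ab <- chisq_overlap(match_events(a, b))
  ba <- chisq_overlap(match_events(b, a))
  expect_equal(ab$chisq, ba$chisq, tolerance = 1e-12)
  expect_identical(ab$n_a_only, ba$n_b_only)
})

test_that("degenerate margins are reported as undefined", {
  keys <- paste0("k", 1:20)
  a <- fake_records(keys, "SE", rep(0.5, 20), 0.1)   # nothing significant
  b <- fake_records(keys, "SE", rep(c(0.01, 0.5), 10), 0.1)
  res <- chisq_overlap(match_events(a, b))
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$chisq)))
})

test_that("direction concordance compares delta-PSI signs", {
  keys <- paste0("k", 1:3)
  a <- fake_records(keys, "SE", c(0.01, 0.01, 0.01), c(0.3, 0.2, -0.1))
  b <- fake_records(keys, "SE", c(0.01, 0.01, 0.01), c(0.5, -0.2, -0.4))
  dc <- direction_concordance(match_events(a, b))
  expect_identical(dc$n_same_direction[dc$event_class == "all"], 2L)
  expect_identical(dc$n_opposite_direction[dc$event_class == "all"], 1L)
  # zero deltas are excluded and counted
  a0 <- fake_records(keys, "SE", rep(0.01, 3), c(0, 0, 0))
  dc0 <- direction_concordance(match_events(a0, b))
  expect_identical(dc0$n_same_direction[1], 0L)
  expect_identical(dc0$n_zero_excluded[1], 3L)
  # a single concordant negative pair
  a1 <- fake_records("k", "RI", 0.01, -0.2)
  b1 <- fake_records("k", "RI", 0.01, -0.5)
  dc1 <- direction_concordance(match_events(a1, b1))
  expect_identical(dc1$n_same_direction[dc1$event_class == "RI"], 1L)
})

test_that("the flag_alpha and Yates options rework the dichotomy", {
  set.seed(9)
  keys <- paste0("k", 1:50)
  a <- fake_records(keys, "SE", runif(50), runif(50, -1, 1))
  b <- fake_records(keys, "SE", runif(50), runif(50, -1, 1))
  u <- match_events(a, b)
  loose <- chisq_overlap(u, flag_alpha = 0.5)
  strict <- chisq_overlap(u, flag_alpha = 0.01)
  expect_gte(loose$n_both[1], strict$n_both[1])
  y <- chisq_overlap(u, flag_alpha = 0.5, correct = TRUE)
  expect_false(isTRUE(all.equal(y$chisq[1], loose$chisq[1])))
})
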