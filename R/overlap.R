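## Cross-dataset comparison of differential-splicing calls.

#' Coordinate-based event keys
#'
#' Events are matched across datasets by what they are, not what they are
#' called: the key is contig, strand, event class and the coordinate
#' tuple.
#'
#' @param events A [splice_events()] table.
#' @return Character vector of keys.
#' @export
event_key <- function(events) {
  paste0(events$contig, ":", events$strand, ":", events$event_class, ":",
         vapply(events$coords, paste, "", collapse = "-"))
}

#' Match differential-splicing results from two datasets
#'
#' The shared universe is the set of events *tested* (non-missing p-value)
#' in both datasets; set `universe = "all"` to keep every matched event.
#' Records are matched on `event_key` (see [event_key()]); both result
#' tables must have been produced with an `events` table supplied to
#' [diff_splicing()].
#'
#' @param records_a,records_b [diff_splicing()] result data frames.
#' @param universe `"tested"` (default) or `"all"`.
#' @return Data frame with one row per shared event: `event_key`,
#'   `event_class`, and `_a`/`_b`-suffixed `delta_psi`, `p_value`,
#'   `q_value`, `significant` columns.
#' @export
match_events <- function(records_a, records_b, universe = c("tested", "all")) {
  universe <- match.arg(universe)
  stopifnot("event_key" %in% names(records_a),
            "event_key" %in% names(records_b))
  keys <- intersect(records_a$event_key, records_b$event_key)
  if (length(keys) == 0L) {
    warning("no shared events between the two result sets")
    return(data.frame(event_key = character(), event_class = character()))
  }
  a <- records_a[match(keys, records_a$event_key), ]
  b <- records_b[match(keys, records_b$event_key), ]
  out <- data.frame(event_key = keys, event_class = a$event_class,
                    delta_psi_a = a$delta_psi, p_value_a = a$p_value,
                    q_value_a = a$q_value, significant_a = a$significant,
                    delta_psi_b = b$delta_psi, p_value_b = b$p_value,
                    q_value_b = b$q_value, significant_b = b$significant,
                    stringsAsFactors = FALSE)
  if (universe == "tested")
    out <- out[!is.na(out$p_value_a) & !is.na(out$p_value_b), ]
  rownames(out) <- NULL
  out
}

pearson_2x2 <- function(tab, correct = FALSE) {
  margins_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (!margins_ok)
    return(list(statistic = NA_real_, p_value = NA_real_,
                degenerate = TRUE, low_count = TRUE, expected = expected))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       degenerate = FALSE, low_count = any(expected < 5), expected = expected)
}

#' Chi-square test of concurrent splicing sensitivity across datasets
#'
#' Per event class (and pooled over all classes), the 2x2 table of
#' significance flags in dataset A versus dataset B over the shared
#' universe is tested for independence with Pearson's chi-square
#' (df = 1, no continuity correction unless `correct = TRUE`).  Classes
#' with a degenerate margin (all-sensitive or all-insensitive in one
#' dataset) report an undefined statistic; classes with any expected cell
#' below 5 are flagged `low_count`.
#'
#' @param universe Data frame from [match_events()].
#' @param alpha Significance threshold applied to the q-values when the
#'   `significant_*` flags need recomputation (`flag_alpha` not `NULL`).
#' @param flag_alpha Optional: re-derive the sensitivity dichotomy as
#'   `q <= flag_alpha` instead of using the stored flags.
#' @param correct Apply Yates continuity correction (default off).
#' @return Data frame per event class (plus `"all"`): table cells
#'   `n_both`, `n_a_only`, `n_b_only`, `n_neither`, `chisq`, `p_value`,
#'   `degenerate`, `low_count`.
#' @export
chisq_overlap <- function(universe, alpha = 0.05, flag_alpha = NULL,
                          correct = FALSE) {
  if (!is.null(flag_alpha)) {
    universe$significant_a <- !is.na(universe$q_value_a) &
      universe$q_value_a <= flag_alpha
    universe$significant_b <- !is.na(universe$q_value_b) &
      universe$q_value_b <= flag_alpha
  }
  groups <- c(list(all = seq_len(nrow(universe))),
              split(seq_len(nrow(universe)), universe$event_class))
  rows <- lapply(names(groups), function(g) {
    u <- universe[groups[[g]], ]
    tab <- table(factor(u$significant_a, levels = c(TRUE, FALSE)),
                 factor(u$significant_b, levels = c(TRUE, FALSE)))
    res <- pearson_2x2(tab, correct = correct)
    data.frame(event_class = g, n = nrow(u),
               n_both = tab[1, 1], n_a_only = tab[1, 2],
               n_b_only = tab[2, 1], n_neither = tab[2, 2],
               chisq = res$statistic, p_value = res$p_value,
               degenerate = res$degenerate, low_count = res$low_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direction concordance of shared significant events
#'
#' Among events significant in both datasets, counts those whose delta-PSI
#' signs agree and disagree; events with a zero delta-PSI in either
#' dataset are excluded and counted separately.
#'
#' @param universe Data frame from [match_events()].
#' @return Data frame per event class (plus `"all"`): `n_significant_both`,
#'   `n_same_direction`, `n_opposite_direction`, `n_zero_excluded`.
#' @export
direction_concordance <- function(universe) {
  sig <- universe[!is.na(universe$significant_a) & universe$significant_a &
                  !is.na(universe$significant_b) & universe$significant_b, ]
  groups <- c(list(all = seq_len(nrow(sig))),
              split(seq_len(nrow(sig)), sig$event_class))
  rows <- lapply(names(groups), function(g) {
    u <- sig[groups[[g]], ]
    zero <- u$delta_psi_a == 0 | u$delta_psi_b == 0
    same <- sign(u$delta_psi_a) == sign(u$delta_psi_b) & !zero
    data.frame(event_class = g,
               n_significant_both = nrow(u),
               n_same_direction = sum(same, na.rm = TRUE),
               n_opposite_direction = sum(!same & !zero, na.rm = TRUE),
               n_zero_excluded = sum(zero, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
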