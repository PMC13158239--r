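## Event-level PSI from transcript abundances, the expression filter, and
## reading-frame consequences.

#' Compute per-event PSI values
#'
#' PSI is the summed TPM of the event's inclusion transcripts divided by
#' the summed TPM of its total transcripts, per sample.  Values are set to
#' missing when the total (denominator) is below `min_total_tpm` — events
#' too weakly expressed to yield a reliable inclusion estimate.
#'
#' @param events A [splice_events()] table.
#' @param tpm Numeric matrix of TPM, transcripts x samples.
#' @param min_total_tpm Minimum total expression per event and sample
#'   (default 10).
#' @return Numeric matrix events x samples with values in \[0, 1\] or `NA`.
#' @export
compute_psi <- function(events, tpm, min_total_tpm = 10) {
  all_tx <- unique(unlist(events$total))
  missing_tx <- setdiff(all_tx, rownames(tpm))
  if (length(missing_tx) > 0L)
    stop("event(s) reference transcripts absent from the abundance matrix: ",
         paste(head(missing_tx, 5L), collapse = ", "))
  psi <- matrix(NA_real_, nrow = nrow(events), ncol = ncol(tpm),
                dimnames = list(events$event_id, colnames(tpm)))
  for (i in seq_len(nrow(events))) {
    inc <- colSums(tpm[events$inclusion[[i]], , drop = FALSE])
    tot <- colSums(tpm[events$total[[i]], , drop = FALSE])
    val <- ifelse(tot >= min_total_tpm, inc / tot, NA_real_)
    psi[i, ] <- val
  }
  psi
}

#' Per-event delta-PSI between conditions
#'
#' Sign convention: `mean(PSI mutant) - mean(PSI wildtype)`, so positive
#' values mean more inclusion in the mutant.  Missing when either condition
#' has no non-missing PSI.
#'
#' @param psi PSI matrix from [compute_psi()].
#' @param design Design data frame (`sample_id`, `condition`).
#' @param conditions Length-2 character: reference (wildtype) and test
#'   (mutant) condition labels.
#' @return Named numeric vector of delta-PSI per event (NA where
#'   unavailable).
#' @export
delta_psi <- function(psi, design,
                      conditions = c("wildtype", "mutant")) {
  stopifnot(length(conditions) == 2L,
            all(conditions %in% design$condition))
  ref <- design$sample_id[design$condition == conditions[1]]
  alt <- design$sample_id[design$condition == conditions[2]]
  m_ref <- rowMeans(psi[, ref, drop = FALSE], na.rm = TRUE)
  m_alt <- rowMeans(psi[, alt, drop = FALSE], na.rm = TRUE)
  d <- m_alt - m_ref
  d[!is.finite(d)] <- NA_real_
  d
}

#' Classify the reading-frame consequence of splicing events
#'
#' The affected length is the skipped-exon length (SE), the retained-intron
#' length (RI) or the absolute shift between the two variant boundaries
#' (A5/A3).  An event is in frame iff that length is a multiple of 3, so
#' inclusion/exclusion isoforms encode the same downstream frame.  MX, AF
#' and AL events are reported `not_applicable` (their isoform pairs differ
#' in more than one local segment).
#'
#' @param events A [splice_events()] table.
#' @return Data frame with `event_id`, `event_class`, `affected_length`,
#'   `frame` (`in_frame`/`out_of_frame`/`not_applicable`).
#' @export
classify_frame <- function(events) {
  len <- vapply(seq_len(nrow(events)), function(i) {
    co <- events$coords[[i]]
    switch(events$event_class[i],
      SE = abs(co[3] - co[2]) + 1L,       # skipped exon length
      RI = abs(co[3] - co[2]) - 1L,       # retained intron length
      A5 = ,
      A3 = abs(co[1] - co[2]),            # boundary shift
      NA_integer_)
  }, integer(1))
  bad <- !is.na(len) & len <= 0L
  if (any(bad))
    stop("coordinates inconsistent with event class for: ",
         paste(events$event_id[bad], collapse = ", "))
  data.frame(event_id = events$event_id,
             event_class = events$event_class,
             affected_length = len,
             frame = ifelse(is.na(len), "not_applicable",
                            ifelse(len %% 3L == 0L, "in_frame",
                                   "out_of_frame")),
             stringsAsFactors = FALSE)
}

#' Summarise significant events by class
#'
#' @param records Data frame with `event_class` and `delta_psi` (typically
#'   the significant subset of a differential-splicing result table).
#' @return Data frame per class: `n`, `percent` (of all records),
#'   `mean_abs_delta_psi`, `mean_delta_psi` (signed).
#' @export
summarise_event_types <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(event_class = character(), n = integer(),
                      percent = numeric(), mean_abs_delta_psi = numeric(),
                      mean_delta_psi = numeric()))
  sp <- split(records$delta_psi, records$event_class)
  out <- data.frame(
    event_class = names(sp),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  out$percent <- 100 * out$n / sum(out$n)
  out$mean_abs_delta_psi <- vapply(sp, function(d) mean(abs(d), na.rm = TRUE),
                                   numeric(1))
  out$mean_delta_psi <- vapply(sp, function(d) mean(d, na.rm = TRUE),
                               numeric(1))
  rownames(out) <- NULL
  out
}
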