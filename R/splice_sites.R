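## Strand-aware splice-site sequence windows and alternative-site geometry.
##
## A window is a fixed-width sequence around one exon|intron boundary, read
## 5'->3' in transcript orientation (minus-strand loci are
## reverse-complemented).  Donor windows cover positions -3..+6 (3 exonic,
## 6 intronic; the boundary falls after position -1); acceptor windows
## cover -8..+2 (8 intronic, 2 exonic; the boundary falls after the
## intron-terminal AG).  Widths are configurable but must cover the
## positions used by the motif statistics (donor -2..+5, acceptor -6..+1).

#' Default splice-site window widths
#'
#' @return Named list: `donor_exon` (3), `donor_intron` (6),
#'   `acceptor_intron` (8), `acceptor_exon` (2).
#' @export
default_window_widths <- function() {
  list(donor_exon = 3L, donor_intron = 6L,
       acceptor_intron = 8L, acceptor_exon = 2L)
}

## boundary = genomic coordinate of the boundary-adjacent *exonic* base
## (last exonic base for donors, first exonic base for acceptors, both in
## transcript orientation)
fetch_window <- function(genome, contig, strand, kind, boundary, widths) {
  if (kind == "donor") { ex <- widths$donor_exon; int <- widths$donor_intron }
  else { ex <- widths$acceptor_exon; int <- widths$acceptor_intron }
  if (strand == "+") {
    from <- if (kind == "donor") boundary - ex + 1L else boundary - int
    to <- if (kind == "donor") boundary + int else boundary + ex - 1L
  } else {
    from <- if (kind == "donor") boundary - int else boundary - ex + 1L
    to <- if (kind == "donor") boundary + ex - 1L else boundary + int
  }
  if (from < 1L || to > length(genome[[contig]]))
    return(NA_character_)
  s <- Biostrings::subseq(genome[[contig]], from, to)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract splice-site sequence windows for events
#'
#' Emits, per event class: A5 — the two variant donor windows plus the
#' shared acceptor; A3 — the two variant acceptors plus the shared donor;
#' SE — the skipped exon's own acceptor and donor plus the flanking
#' upstream donor and downstream acceptor; RI — the retained intron's
#' donor and acceptor.  MX/AF/AL events are skipped.  Variant roles are
#' `original`/`alternative`; by default variant 1 (the inclusion-form
#' boundary, first in the annotation) is `original` — pass `original_variant`
#' (from [site_distance()]) to use control-condition PSI dominance instead.
#'
#' Windows extending beyond the contig are dropped with a warning; windows
#' containing N are kept but flagged (`contains_N`) and excluded from
#' position matrices downstream.
#'
#' @param events A [splice_events()] table.
#' @param genome A [Biostrings::DNAStringSet].
#' @param original_variant Optional named integer vector (event_id -> 1 or
#'   2) giving the control-dominant variant for A5/A3 events.
#' @param widths Window widths, see [default_window_widths()].
#' @return Data frame with `event_id`, `event_class`, `site_kind`, `role`,
#'   `contig`, `strand`, `boundary`, `sequence`, `contains_N`; window
#'   widths stored in `attr(, "widths")`.
#' @export
extract_site_windows <- function(events, genome, original_variant = NULL,
                                 widths = default_window_widths()) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    cls <- events$event_class[i]
    co <- events$coords[[i]]
    ov <- 1L
    if (!is.null(original_variant) &&
        events$event_id[i] %in% names(original_variant))
      ov <- original_variant[[events$event_id[i]]]
    vroles <- if (ov == 1L) c("original", "alternative")
              else c("alternative", "original")
    sites <- switch(cls,
      SE = data.frame(kind = c("donor", "acceptor", "donor", "acceptor"),
                      role = c("upstream-flank", "canonical", "canonical",
                               "downstream-flank"),
                      boundary = co[c(1L, 2L, 3L, 4L)]),
      RI = data.frame(kind = c("donor", "acceptor"),
                      role = c("canonical", "canonical"),
                      boundary = co[c(2L, 3L)]),
      A5 = data.frame(kind = c("donor", "donor", "acceptor"),
                      role = c(vroles, "anchor"),
                      boundary = co[c(1L, 2L, 3L)]),
      A3 = data.frame(kind = c("acceptor", "acceptor", "donor"),
                      role = c(vroles, "anchor"),
                      boundary = co[c(1L, 2L, 3L)]),
      NULL)
    if (is.null(sites)) next
    sites$event_id <- events$event_id[i]
    sites$event_class <- cls
    sites$contig <- events$contig[i]
    sites$strand <- events$strand[i]
    rows[[length(rows) + 1L]] <- sites
  }
  win <- do.call(rbind, rows)
  if (is.null(win))
    win <- data.frame(kind = character(), role = character(),
                      boundary = integer(), event_id = character(),
                      event_class = character(), contig = character(),
                      strand = character())
  win$sequence <- vapply(seq_len(nrow(win)), function(j)
    fetch_window(genome, win$contig[j], win$strand[j], win$kind[j],
                 win$boundary[j], widths), character(1))
  dropped <- is.na(win$sequence)
  if (any(dropped)) {
    warning(sum(dropped), " window(s) beyond contig bounds dropped")
    win <- win[!dropped, ]
  }
  win$contains_N <- grepl("N", win$sequence, fixed = TRUE)
  out <- data.frame(event_id = win$event_id, event_class = win$event_class,
                    site_kind = win$kind, role = win$role,
                    contig = win$contig, strand = win$strand,
                    boundary = win$boundary, sequence = win$sequence,
                    contains_N = win$contains_N, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "widths") <- widths
  out
}

#' Extract windows for every annotated splice site
#'
#' All intron boundaries of all transcripts in the annotation, deduplicated
#' by genomic position; used as the background site set for the strength
#' model.
#'
#' @param annotation A [tx_annotation()] data frame.
#' @param genome A [Biostrings::DNAStringSet].
#' @param widths Window widths.
#' @return Data frame as in [extract_site_windows()] (roles `annotated`).
#' @export
annotated_site_windows <- function(annotation, genome,
                                   widths = default_window_widths()) {
  intr <- tx_introns(annotation)
  ## boundary-adjacent exonic base: donor is before the intron in
  ## transcript orientation, acceptor after
  don <- data.frame(contig = intr$contig, strand = intr$strand,
                    kind = "donor",
                    boundary = ifelse(intr$strand == "+", intr$start - 1L,
                                      intr$end + 1L))
  acc <- data.frame(contig = intr$contig, strand = intr$strand,
                    kind = "acceptor",
                    boundary = ifelse(intr$strand == "+", intr$end + 1L,
                                      intr$start - 1L))
  win <- unique(rbind(don, acc))
  win$sequence <- vapply(seq_len(nrow(win)), function(j)
    fetch_window(genome, win$contig[j], win$strand[j], win$kind[j],
                 win$boundary[j], widths), character(1))
  win <- win[!is.na(win$sequence), ]
  out <- data.frame(event_id = NA_character_, event_class = NA_character_,
                    site_kind = win$kind, role = "annotated",
                    contig = win$contig, strand = win$strand,
                    boundary = win$boundary, sequence = win$sequence,
                    contains_N = grepl("N", win$sequence, fixed = TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "widths") <- widths
  out
}

#' Base at a splice-site-relative position
#'
#' Positions are negative on the exon side and positive on the intron side
#' for donors (-3..-1 | +1..+6), negative on the intron side and positive
#' on the exon side for acceptors (-8..-1 | +1..+2); there is no
#' position 0.
#'
#' @param windows Window data frame (one `site_kind` throughout).
#' @param pos Integer position.
#' @param widths Window widths used at extraction.
#' @return Character vector of bases.
#' @export
window_base <- function(windows, pos, widths = attr(windows, "widths")) {
  if (is.null(widths)) widths <- default_window_widths()
  kind <- unique(windows$site_kind)
  stopifnot(length(kind) == 1L, pos != 0L)
  before <- if (kind == "donor") widths$donor_exon else widths$acceptor_intron
  idx <- before + pos + as.integer(pos < 0L)
  substr(windows$sequence, idx, idx)
}

#' Alternative-site geometry for A5/A3 events
#'
#' The signed distance from the original to the alternative boundary, in
#' transcript orientation (positive = downstream of the original site).
#' The "original" site is the variant with higher mean PSI in the control
#' condition; variant 1 is the event's inclusion-form boundary, so control
#' mean PSI > 0.5 means variant 1 is original (ties resolve to variant 1,
#' the annotation-first variant, with a message).  Without PSI data,
#' variant 1 is taken as original.
#'
#' @param events A [splice_events()] table (A5/A3 rows are used).
#' @param psi Optional PSI matrix from [compute_psi()].
#' @param design Optional design data frame (required with `psi`).
#' @param control Control condition label.
#' @return Data frame with `event_id`, `event_class`, `original_variant`,
#'   `distance`, `direction` (`upstream`/`downstream`), `periodicity_class`
#'   (distance mod 3).
#' @export
site_distance <- function(events, psi = NULL, design = NULL,
                          control = "wildtype") {
  sel <- events$event_class %in% c("A5", "A3")
  ev <- events[sel, ]
  if (nrow(ev) == 0L)
    return(data.frame(event_id = character(), event_class = character(),
                      original_variant = integer(), distance = integer(),
                      direction = character(), periodicity_class = integer()))
  orig <- rep(1L, nrow(ev))
  if (!is.null(psi)) {
    stopifnot(!is.null(design))
    ctrl_cols <- design$sample_id[design$condition == control]
    m <- rowMeans(psi[ev$event_id, ctrl_cols, drop = FALSE], na.rm = TRUE)
    tie <- is.na(m) | m == 0.5
    if (any(tie))
      message(sum(tie), " A5/A3 event(s) with tied/undefined control PSI; ",
              "variant 1 (annotation-first) taken as original")
    orig <- ifelse(!tie & m < 0.5, 2L, 1L)
  }
  v1 <- vapply(ev$coords, `[`, integer(1), 1L)
  v2 <- vapply(ev$coords, `[`, integer(1), 2L)
  ob <- ifelse(orig == 1L, v1, v2)
  ab <- ifelse(orig == 1L, v2, v1)
  sgn <- ifelse(ev$strand == "+", 1L, -1L)
  dist <- (ab - ob) * sgn
  data.frame(event_id = ev$event_id, event_class = ev$event_class,
             original_variant = orig, distance = as.integer(dist),
             direction = ifelse(dist > 0, "downstream", "upstream"),
             periodicity_class = as.integer(dist %% 3L),
             stringsAsFactors = FALSE)
}

#' Distance histogram and 3-nt periodicity test
#'
#' @param geometries Data frame from [site_distance()].
#' @return List with `distance_table` (counts per signed distance),
#'   `residue_counts` (counts of distance mod 3 = 0, 1, 2),
#'   `fraction_in_frame` (residue 0), and `chisq` (statistic, df = 2,
#'   p-value of the goodness-of-fit test against uniform residue classes).
#' @export
periodicity_summary <- function(geometries) {
  stopifnot(nrow(geometries) >= 1L)
  res <- factor(geometries$periodicity_class, levels = 0:2)
  counts <- as.vector(table(res))
  n <- sum(counts)
  expected <- rep(n / 3, 3L)
  stat <- sum((counts - expected)^2 / expected)
  list(distance_table = table(geometries$distance),
       residue_counts = setNames(counts, c("mod0", "mod1", "mod2")),
       fraction_in_frame = counts[1] / n,
       chisq = list(statistic = stat, df = 2L,
                    p_value = pchisq(stat, 2L, lower.tail = FALSE)))
}
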