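## Position matrices, information content, G-test motif comparison, U5/U6
## contingency classes, site-strength scoring and strong/weak shift
## categories.

BASES <- c("A", "C", "G", "T")

#' Build a position frequency/probability matrix from sequence windows
#'
#' N-flagged windows are excluded.  Per-column information content is
#' `2 + sum_b p_b log2 p_b` bits (0 log 0 := 0), without small-sample
#' correction.
#'
#' @param windows Window data frame (or character vector of equal-width
#'   sequences).
#' @return List of class `"position_matrix"` with `pfm` (4 x width
#'   counts), `ppm` (probabilities), `ic` (bits per column),
#'   `n_sequences`.
#' @export
build_pfm <- function(windows) {
  seqs <- if (is.character(windows)) windows
          else windows$sequence[!windows$contains_N]
  seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  if (length(seqs) == 0L) stop("no N-free sequences to build a PFM from")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("windows have mixed widths")
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                byrow = TRUE)
  pfm <- vapply(seq_len(w), function(j)
    tabulate(factor(mat[, j], levels = BASES), nbins = 4L), integer(4))
  dimnames(pfm) <- list(BASES, seq_len(w))
  ppm <- sweep(pfm, 2L, colSums(pfm), "/")
  plogp <- ifelse(ppm > 0, ppm * log2(ppm), 0)
  structure(list(pfm = pfm, ppm = ppm, ic = 2 + colSums(plogp),
                 n_sequences = length(seqs)),
            class = "position_matrix")
}

#' Likelihood-ratio (G) test of independence on a count table
#'
#' `G = 2 sum O ln(O/E)` with expected counts from the margins and a
#' chi-square reference.  Cells with zero observed count contribute 0;
#' rows/columns empty in both margins are dropped with a matching
#' reduction in degrees of freedom.
#'
#' @param tab Numeric matrix of counts.
#' @return List with `statistic`, `df`, `p_value` (`statistic = 0`,
#'   `p = 1` when only one category remains; all `NA` when an entire
#'   row margin is empty).
#' @export
gtest_table <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L)   # a whole set empty: no comparison to make
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  if (ncol(tab) < 2L)   # both sets concentrate on one category: no signal
    return(list(statistic = 0, df = 0L, p_value = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  g <- 2 * sum(terms)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = g, df = df,
       p_value = pchisq(g, df, lower.tail = FALSE))
}

#' G-test comparison of two position matrices
#'
#' Likelihood-ratio test of base composition between two window sets,
#' position by position, on the 2 x 4 (set x base) count table; expected
#' counts come from the table margins, zero observed cells contribute 0
#' and bases absent from both sets are dropped with a matching reduction
#' in degrees of freedom.  The whole-motif statistic is the sum over
#' positions.
#'
#' @param pfm_a,pfm_b [build_pfm()] results of equal width.
#' @return List with `per_position` (data frame: position, G, df, p_value)
#'   and `overall` (summed G, df, p_value).
#' @export
gtest_motif <- function(pfm_a, pfm_b) {
  ca <- pfm_a$pfm; cb <- pfm_b$pfm
  if (ncol(ca) == 0L || ncol(cb) == 0L) stop("empty position matrix")
  if (ncol(ca) != ncol(cb)) stop("position matrices differ in width")
  per <- lapply(seq_len(ncol(ca)), function(j)
    gtest_table(rbind(a = ca[, j], b = cb[, j])))
  pp <- data.frame(position = seq_len(ncol(ca)),
                   G = vapply(per, `[[`, numeric(1), "statistic"),
                   df = vapply(per, function(x) as.numeric(x$df), numeric(1)),
                   p_value = vapply(per, `[[`, numeric(1), "p_value"))
  g <- sum(pp$G, na.rm = TRUE)
  df <- sum(pp$df, na.rm = TRUE)
  list(per_position = pp,
       overall = list(statistic = g, df = df,
                      p_value = if (df == 0) 1
                                else pchisq(g, df, lower.tail = FALSE)))
}

#' Classify donor windows by U5/U6 interacting positions
#'
#' The U5 snRNA loop pairs with the exonic -2,-1 positions (consensus AG);
#' U6 snRNA pairs with the intronic +3..+5 positions (consensus RAG,
#' R = A/G).  Each window is assigned a joint class such as
#' `"u5_consensus/u6_deviant"`.
#'
#' @param donor_windows Donor window data frame.
#' @return The input with `u5_state`, `u6_state` (`consensus`/`deviant`),
#'   `u5_seq`, `u6_seq` and `joint_class` columns.
#' @export
classify_u5_u6 <- function(donor_windows) {
  if (nrow(donor_windows) > 0 && !all(donor_windows$site_kind == "donor"))
    stop("classify_u5_u6 expects donor windows only")
  w <- donor_windows
  b_m2 <- window_base(w, -2L); b_m1 <- window_base(w, -1L)
  b_p3 <- window_base(w, 3L); b_p4 <- window_base(w, 4L)
  b_p5 <- window_base(w, 5L)
  w$u5_seq <- paste0(b_m2, b_m1)
  w$u6_seq <- paste0(b_p3, b_p4, b_p5)
  w$u5_state <- ifelse(w$u5_seq == "AG", "consensus", "deviant")
  w$u6_state <- ifelse(b_p3 %in% c("A", "G") & b_p4 == "A" & b_p5 == "G",
                       "consensus", "deviant")
  w$joint_class <- paste0("u5_", w$u5_state, "/u6_", w$u6_state)
  w
}

#' U5/U6 contingency table between two donor-window sets
#'
#' Cross-tabulates the four joint U5/U6 classes against window set and
#' tests independence with both the G-test and Pearson's chi-square.
#'
#' @param windows_a,windows_b Donor window data frames.
#' @param labels Length-2 set labels for the columns.
#' @return List with `table` (4 x 2 counts), `gtest`, `chisq`.
#' @export
u5u6_contingency <- function(windows_a, windows_b,
                             labels = c("set_a", "set_b")) {
  lv <- c("u5_consensus/u6_consensus", "u5_consensus/u6_deviant",
          "u5_deviant/u6_consensus", "u5_deviant/u6_deviant")
  ca <- table(factor(classify_u5_u6(windows_a)$joint_class, levels = lv))
  cb <- table(factor(classify_u5_u6(windows_b)$joint_class, levels = lv))
  tab <- cbind(ca, cb)
  colnames(tab) <- labels
  chis <- suppressWarnings(chisq.test(tab[rowSums(tab) > 0, , drop = FALSE],
                                      correct = FALSE))
  list(table = tab, gtest = gtest_table(tab),
       chisq = list(statistic = unname(chis$statistic),
                    df = unname(chis$parameter),
                    p_value = chis$p.value))
}

#' Cross-tabulation of U5 dinucleotides by U6 trinucleotides
#'
#' The heatmap-style table of observed -2,-1 dinucleotide against +3..+5
#' trinucleotide strings, restricted to the top-k most frequent of each.
#'
#' @param donor_windows Donor window data frame.
#' @param top_k Number of rows/columns to keep (default 8).
#' @return Integer matrix, U5 dinucleotides x U6 trinucleotides.
#' @export
u5u6_crosstab <- function(donor_windows, top_k = 8L) {
  cl <- classify_u5_u6(donor_windows)
  u5 <- names(sort(table(cl$u5_seq), decreasing = TRUE))
  u6 <- names(sort(table(cl$u6_seq), decreasing = TRUE))
  u5 <- head(u5, top_k); u6 <- head(u6, top_k)
  tab <- table(factor(cl$u5_seq, levels = u5),
               factor(cl$u6_seq, levels = u6))
  unclass(as.matrix(tab))
}

#' Fit a splice-site strength model from annotated sites
#'
#' The model is a log-odds score of the annotated-site position
#' probability matrix against a uniform background, with probabilities
#' floored at `p_floor`.  The strong/weak threshold is derived from the
#' annotated sites' own scores.  The default (`"mixture"`) fits a
#' two-component unequal-variance Gaussian mixture to the scores (the
#' consensus-like mode is narrow, the deviant mode wide) and thresholds
#' midway between the two classified groups where they meet; `"median"`
#' uses the annotated median instead (labelling half of the annotated
#' sites strong by construction).
#'
#' @param annotated_windows Windows of one site kind (typically from
#'   [annotated_site_windows()]).
#' @param p_floor Probability floor (default 1e-3).
#' @param threshold Optional fixed threshold in bits (overrides
#'   `threshold_method`).
#' @param threshold_method `"mixture"` (default) or `"median"`.
#' @return List of class `"strength_model"` with `pfm`, `site_kind`,
#'   `p_floor`, `threshold`, `scores` (of the annotated sites).
#' @export
build_strength_model <- function(annotated_windows, p_floor = 1e-3,
                                 threshold = NULL,
                                 threshold_method = c("mixture", "median")) {
  threshold_method <- match.arg(threshold_method)
  kind <- unique(annotated_windows$site_kind)
  stopifnot(length(kind) == 1L)
  pm <- build_pfm(annotated_windows)
  model <- structure(list(pfm = pm, site_kind = kind, p_floor = p_floor,
                          threshold = NULL),
                     class = "strength_model")
  scores <- strength_scores(annotated_windows, model)
  ok <- scores[!is.na(scores)]
  if (is.null(threshold)) {
    threshold <- if (threshold_method == "mixture")
      mixture_split(ok) else median(ok)
  }
  model$threshold <- threshold
  model$scores <- scores
  message("site-strength threshold (", kind, "): ",
          format(model$threshold, digits = 4L), " bits (",
          threshold_method, " of annotated-site scores)")
  model
}

## two-component 1-D Gaussian mixture split; falls back to the median when
## the scores carry too little structure for a mixture fit
mixture_split <- function(scores) {
  if (length(unique(scores)) < 10L) return(median(scores))
  mc <- tryCatch(
    mclust::Mclust(scores, G = 2L, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(mc) || length(unique(mc$classification)) < 2L)
    return(median(scores))
  hi <- which.max(mc$parameters$mean)
  (max(scores[mc$classification != hi]) +
     min(scores[mc$classification == hi])) / 2
}

strength_scores <- function(windows, model) {
  ppm <- pmax(model$pfm$ppm, model$p_floor)
  w <- ncol(ppm)
  vapply(windows$sequence, function(s) {
    if (nchar(s) != w) stop("window width does not match the strength model")
    b <- strsplit(s, "")[[1]]
    if (any(!b %in% BASES)) return(NA_real_)
    sum(log2(ppm[cbind(b, seq_len(w))] / 0.25))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score splice-site strength and label strong/weak
#'
#' @param windows Window data frame (same site kind as the model).
#' @param model A [build_strength_model()].
#' @return The input with `score` (log-odds bits) and `label`
#'   (`strong` iff score >= threshold) columns; N-containing windows score
#'   `NA` and are left unlabelled.
#' @export
score_site_strength <- function(windows, model) {
  stopifnot(inherits(model, "strength_model"),
            all(windows$site_kind == model$site_kind))
  windows$score <- strength_scores(windows, model)
  windows$label <- ifelse(is.na(windows$score), NA_character_,
                          ifelse(windows$score >= model$threshold,
                                 "strong", "weak"))
  windows
}

#' Categorise strong/weak shifts between original and alternative sites
#'
#' Each pair is oriented by the direction of usage gain in the mutant: the
#' category reads losing-site label to gaining-site label.  For A5/A3
#' events the alternative site gains usage when the event's delta-PSI is
#' negative (variant-1/original inclusion drops) and vice versa.  A shift
#' is "complete" when the losing site's mutant-condition PSI falls at or
#' below `complete_psi` (default 0.05).
#'
#' @param pairs Data frame with columns `event_id`, `original_label`,
#'   `alternative_label`, `delta_psi` (original-form inclusion, mutant -
#'   wildtype) and optionally `losing_site_mutant_psi`.
#' @param complete_psi Complete-shift threshold on the losing site's
#'   mutant PSI.
#' @return List with `pairs` (per-event `shift` and `complete` columns)
#'   and `counts` (table over the four categories).
#' @export
classify_shifts <- function(pairs, complete_psi = 0.05) {
  need <- c("event_id", "original_label", "alternative_label", "delta_psi")
  if (!all(need %in% names(pairs)))
    stop("pairs need columns: ", paste(need, collapse = ", "))
  alt_gains <- pairs$delta_psi < 0
  from <- ifelse(alt_gains, pairs$original_label, pairs$alternative_label)
  to <- ifelse(alt_gains, pairs$alternative_label, pairs$original_label)
  pairs$shift <- ifelse(is.na(from) | is.na(to), NA_character_,
                        paste0(from, "->", to))
  if (!is.null(pairs$losing_site_mutant_psi))
    pairs$complete <- !is.na(pairs$losing_site_mutant_psi) &
      pairs$losing_site_mutant_psi <= complete_psi
  lv <- c("strong->strong", "strong->weak", "weak->strong", "weak->weak")
  counts <- table(factor(pairs$shift, levels = lv))
  list(pairs = pairs, counts = counts)
}
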