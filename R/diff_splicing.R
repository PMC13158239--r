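## Per-event association testing between genotype and PSI with BH FDR
## control.

#' Fit the per-event genotype model
#'
#' Gaussian-family, identity-link GLM `PSI ~ genotype` with the two-sided
#' t-reference on the genotype coefficient (n - 2 degrees of freedom),
#' which for a two-level factor is the pooled two-sample t-test.  The
#' coefficient equals the delta-PSI (test minus reference condition mean).
#'
#' Zero residual variance is handled by convention: p = 1 when the
#' coefficient is also (numerically) zero, p = 0 otherwise.
#'
#' @param psi_values Numeric PSI vector for one event (NA allowed).
#' @param condition Character/factor of condition labels, same length.
#' @param conditions Length-2 character: reference then test level.
#' @return List with `coefficient`, `p_value`, `t`, `df` (all `NA` when a
#'   condition has fewer than two non-missing values).
#' @export
fit_event_glm <- function(psi_values, condition,
                          conditions = c("wildtype", "mutant")) {
  keep <- !is.na(psi_values) & condition %in% conditions
  y <- psi_values[keep]
  g <- factor(condition[keep], levels = conditions)
  if (any(table(g) < 2L))
    return(list(coefficient = NA_real_, p_value = NA_real_,
                t = NA_real_, df = NA_integer_))
  fit <- glm(y ~ g, family = gaussian())
  coef_ <- unname(coef(fit)[2L])
  df <- fit$df.residual
  rss <- sum(fit$residuals^2)
  if (rss < 1e-24) {
    p <- if (abs(coef_) < 1e-12) 1 else 0
    return(list(coefficient = coef_, p_value = p,
                t = if (p == 1) 0 else Inf, df = df))
  }
  sm <- summary(fit)$coefficients
  list(coefficient = coef_, p_value = unname(sm[2L, 4L]),
       t = unname(sm[2L, 3L]), df = df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; missing p-values are excluded from the number of
#' tests `m` (untestable hypotheses do not dilute the correction) and stay
#' missing in the output.
#'
#' @param p_values Numeric vector in \[0, 1\], NA allowed.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

## vectorised pooled two-sample t statistics for a PSI matrix; algebraically
## identical to fit_event_glm per row (verified by tests)
pooled_t_rows <- function(psi, ref_cols, alt_cols) {
  n1 <- rowSums(!is.na(psi[, ref_cols, drop = FALSE]))
  n2 <- rowSums(!is.na(psi[, alt_cols, drop = FALSE]))
  m1 <- rowMeans(psi[, ref_cols, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(psi[, alt_cols, drop = FALSE], na.rm = TRUE)
  ss1 <- rowSums((psi[, ref_cols, drop = FALSE] - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((psi[, alt_cols, drop = FALSE] - m2)^2, na.rm = TRUE)
  tested <- n1 >= 2L & n2 >= 2L
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  est <- m2 - m1
  t <- est / se
  p <- 2 * pt(-abs(t), df)
  ## zero-residual-variance convention
  degen <- tested & (ss1 + ss2) < 1e-24
  p[degen] <- ifelse(abs(est[degen]) < 1e-12, 1, 0)
  t[degen] <- ifelse(abs(est[degen]) < 1e-12, 0, Inf)
  p[!tested] <- NA_real_
  t[!tested] <- NA_real_
  est[!tested] <- NA_real_
  data.frame(delta_psi = est, t = t, df = ifelse(tested, df, NA), p_value = p)
}

#' Differential splicing across all events
#'
#' Applies the per-event genotype model to every row of a PSI matrix,
#' adjusts p-values with Benjamini-Hochberg FDR and flags significance at
#' `alpha`.  An optional absolute delta-PSI floor is available but off by
#' default (significance is FDR-only).
#'
#' @param psi PSI matrix from [compute_psi()].
#' @param design Design data frame.
#' @param events Optional [splice_events()] table; adds `event_class` and a
#'   coordinate-based `event_key` for cross-dataset matching.
#' @param alpha FDR threshold (default 0.05).
#' @param min_abs_delta_psi Optional effect-size floor (default 0).
#' @param conditions Reference and test condition labels.
#' @return Data frame with `event_id`, `event_class`, `delta_psi`,
#'   `p_value`, `q_value`, `significant`.
#' @export
diff_splicing <- function(psi, design, events = NULL, alpha = 0.05,
                          min_abs_delta_psi = 0,
                          conditions = c("wildtype", "mutant")) {
  stopifnot(all(conditions %in% design$condition))
  ref <- design$sample_id[design$condition == conditions[1]]
  alt <- design$sample_id[design$condition == conditions[2]]
  if (length(ref) < 2L || length(alt) < 2L)
    stop("need >= 2 samples per condition")
  res <- pooled_t_rows(psi, ref, alt)
  out <- data.frame(event_id = rownames(psi), res,
                    stringsAsFactors = FALSE)
  out$q_value <- bh_fdr(out$p_value)
  if (!is.null(events)) {
    idx <- match(out$event_id, events$event_id)
    out$event_class <- events$event_class[idx]
    out$event_key <- event_key(events)[idx]
    out <- out[, c("event_id", "event_class", "event_key", "delta_psi",
                   "t", "df", "p_value", "q_value")]
  }
  call_significant(out, alpha = alpha,
                   min_abs_delta_psi = min_abs_delta_psi)
}

#' Flag significant events
#'
#' Significant iff the q-value is at most `alpha`, delta-PSI is
#' non-missing, and (when a floor is set) |delta-PSI| reaches the floor.
#'
#' @param records Data frame with `q_value` and `delta_psi`.
#' @param alpha FDR threshold.
#' @param min_abs_delta_psi Optional effect-size floor (default 0 — off).
#' @return `records` with a logical `significant` column.
#' @export
call_significant <- function(records, alpha = 0.05, min_abs_delta_psi = 0) {
  records$significant <- !is.na(records$q_value) &
    !is.na(records$delta_psi) &
    records$q_value <= alpha &
    abs(records$delta_psi) >= min_abs_delta_psi
  records
}

#' Intersect differentially spliced and differentially expressed gene sets
#'
#' @param ds_genes Character vector of differentially spliced gene ids.
#' @param de_genes Character vector of differentially expressed gene ids.
#' @return List with `shared` (sorted intersection), `n_ds`, `n_de`,
#'   `n_shared`.
#' @export
intersect_gene_sets <- function(ds_genes, de_genes) {
  shared <- sort(intersect(unique(ds_genes), unique(de_genes)))
  list(shared = shared, n_ds = length(unique(ds_genes)),
       n_de = length(unique(de_genes)), n_shared = length(shared))
}
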