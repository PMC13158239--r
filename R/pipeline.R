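## End-to-end orchestration: simulate -> write inputs -> re-read through
## the parsers -> PSI -> differential splicing -> frames -> site windows,
## geometry and motif statistics, with a JSON run manifest.

#' Run the full splicing-analysis pipeline on a simulated dataset
#'
#' Generates a dataset from `config`, writes the input files
#' (FASTA/GTF/ioe/TSV), reads them back through the package parsers (so
#' the run exercises the same code paths as an external dataset), and
#' computes every analysis table.  Identical `config` (including seed)
#' gives byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param alpha FDR threshold (default 0.05).
#' @param min_total_tpm Expression filter for PSI (default 10).
#' @param widths Splice-site window widths.
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         alpha = 0.05, min_total_tpm = 10,
                         widths = default_window_widths()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_splicing_dataset(config)
  inputs <- write_simulation(sim, out_dir)

  genome <- read_fasta(inputs["genome"])
  annotation <- read_gtf(inputs["annotation"])
  events <- read_ioe(inputs["events"])
  tpm <- read_tpm(inputs["tpm"])
  design <- read_design(inputs["design"])

  par_comment <- c(
    paste0("spliceflow ", packageVersion("spliceflow")),
    paste0("seed=", config$seed, " alpha=", alpha,
           " min_total_tpm=", min_total_tpm,
           " delta_psi_convention=mutant-minus-wildtype"))

  psi <- compute_psi(events, tpm, min_total_tpm = min_total_tpm)
  frames <- classify_frame(events)
  ds <- diff_splicing(psi, design, events = events, alpha = alpha)
  ds$frame <- frames$frame[match(ds$event_id, frames$event_id)]
  summary_tab <- summarise_event_types(ds[ds$significant, ])

  geom <- suppressMessages(site_distance(events, psi, design))
  orig <- setNames(geom$original_variant, geom$event_id)
  windows <- extract_site_windows(events, genome, original_variant = orig,
                                 widths = widths)
  per <- if (nrow(geom) > 0L) periodicity_summary(geom) else NULL

  bg_don <- annotated_site_windows(annotation, genome, widths = widths)
  don_model <- suppressMessages(
    build_strength_model(bg_don[bg_don$site_kind == "donor", ]))
  acc_model <- suppressMessages(
    build_strength_model(bg_don[bg_don$site_kind == "acceptor", ]))
  windows <- rbind(
    score_site_strength(windows[windows$site_kind == "donor", ], don_model),
    score_site_strength(windows[windows$site_kind == "acceptor", ], acc_model))

  shifts <- shift_pairs(windows, ds, psi, design, original_variant = orig)
  shift_res <- if (nrow(shifts) > 0L) classify_shifts(shifts) else NULL

  sens <- windows[!is.na(windows$event_id) & windows$role == "original" &
                  windows$site_kind == "donor", ]
  altw <- windows[!is.na(windows$event_id) & windows$role == "alternative" &
                  windows$site_kind == "donor", ]
  u5u6 <- if (nrow(sens) > 0L && nrow(altw) > 0L)
    u5u6_contingency(sens, altw, labels = c("original", "alternative"))
  else NULL

  write_table(ds, file.path(out_dir, "diff_splicing.tsv"), par_comment)
  write_table(frames, file.path(out_dir, "frames.tsv"), par_comment)
  write_table(summary_tab, file.path(out_dir, "event_type_summary.tsv"),
              par_comment)
  write_table(data.frame(event_id = rownames(psi), psi,
                         check.names = FALSE),
              file.path(out_dir, "psi.tsv"), par_comment)
  write_table(windows, file.path(out_dir, "site_windows.tsv"), par_comment)
  write_table(geom, file.path(out_dir, "site_geometry.tsv"), par_comment)
  if (!is.null(shift_res))
    write_table(shift_res$pairs, file.path(out_dir, "strength_shifts.tsv"),
                par_comment)
  if (!is.null(u5u6))
    write_table(data.frame(joint_class = rownames(u5u6$table),
                           u5u6$table, check.names = FALSE),
                file.path(out_dir, "u5u6_table.tsv"), par_comment)

  outputs <- list.files(out_dir, pattern = "\\.tsv$|\\.fa$|\\.gtf$|\\.ioe$",
                        full.names = TRUE)
  manifest <- list(
    package = "spliceflow",
    version = as.character(packageVersion("spliceflow")),
    seed = config$seed,
    parameters = list(alpha = alpha, min_total_tpm = min_total_tpm,
                      n_genes = config$n_genes,
                      n_replicates = config$n_replicates,
                      true_delta_psi = config$true_delta_psi,
                      fraction_affected = config$fraction_affected,
                      psi_noise_sd = config$psi_noise_sd,
                      strong_site_fraction = config$strong_site_fraction,
                      depth_scale = config$depth_scale),
    checksums = as.list(md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, psi = psi, diff = ds, frames = frames,
                 summary = summary_tab, windows = windows, geometry = geom,
                 periodicity = per, shifts = shift_res, u5u6 = u5u6,
                 donor_model = don_model, acceptor_model = acc_model,
                 manifest = manifest))
}

#' Build original/alternative strength pairs for A5/A3 events
#'
#' Joins scored variant windows with the differential-splicing table and
#' derives, per event, the original-form delta-PSI and the losing site's
#' mutant-condition PSI.  The event PSI tracks variant 1 (the
#' inclusion-form boundary), so when the original site is variant 2 both
#' the delta-PSI and the usage values are complemented.
#'
#' @param scored_windows Windows with `score`/`label` columns (roles
#'   `original`/`alternative`).
#' @param ds [diff_splicing()] result table.
#' @param psi PSI matrix.
#' @param design Design data frame.
#' @param original_variant Named integer vector (event_id -> 1 or 2), as
#'   produced by [site_distance()]; defaults to variant 1 for all events.
#' @param mutant Test condition label.
#' @return Data frame suitable for [classify_shifts()].
#' @export
shift_pairs <- function(scored_windows, ds, psi, design,
                        original_variant = NULL, mutant = "mutant") {
  w <- scored_windows[scored_windows$role %in% c("original", "alternative"), ]
  w <- w[w$event_class %in% c("A5", "A3"), ]
  if (nrow(w) == 0L) return(data.frame())
  ow <- w[w$role == "original", ]
  aw <- w[w$role == "alternative", ]
  ids <- intersect(ow$event_id, aw$event_id)
  ow <- ow[match(ids, ow$event_id), ]
  aw <- aw[match(ids, aw$event_id), ]
  orig <- rep(1L, length(ids))
  if (!is.null(original_variant)) {
    hit <- ids %in% names(original_variant)
    orig[hit] <- original_variant[ids[hit]]
  }
  d_v1 <- ds$delta_psi[match(ids, ds$event_id)]
  d_orig <- ifelse(orig == 1L, d_v1, -d_v1)
  mut_cols <- design$sample_id[design$condition == mutant]
  psi_mut_v1 <- rowMeans(psi[ids, mut_cols, drop = FALSE], na.rm = TRUE)
  orig_mut <- ifelse(orig == 1L, psi_mut_v1, 1 - psi_mut_v1)
  pairs <- data.frame(event_id = ids,
                      event_class = ow$event_class,
                      original_label = ow$label,
                      alternative_label = aw$label,
                      delta_psi = d_orig,
                      stringsAsFactors = FALSE)
  ## losing site = original when its usage drops in the mutant
  pairs$losing_site_mutant_psi <- ifelse(d_orig < 0, orig_mut, 1 - orig_mut)
  pairs[!is.na(pairs$delta_psi), ]
}
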