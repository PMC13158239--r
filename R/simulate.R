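## Synthetic two-condition splicing datasets with a known truth table.
##
## Each gene hosts exactly one alternative-splicing event realised by two
## isoforms (inclusion/exclusion).  Gene structures are laid out in
## transcript ("sense") coordinates, splice-site motifs are stamped at the
## junctions, and the sense sequence is placed on the genome forward or
## reverse-complemented according to the gene's strand — so minus-strand
## handling is exercised end to end.
##
## Splice-site sequence model (DNA alphabet):
##   donor (5'SS):    exonic -2,-1 = AG | intronic +1,+2 = GT, +3 = A/G (R),
##                    +4 = A, +5 = G   (the GURAGU consensus, written in DNA)
##   acceptor (3'SS): intronic -6..-1 = TTTCAG | exonic +1 = A/G (R)
##                    (the UUUCAG/R consensus, written in DNA)
## "Strong" sites match the consensus at every key position; "weak" sites
## deviate at >= 1 of the U5 (-2,-1) or U6 (+3..+5) donor positions, or at
## >= 1 non-AG acceptor consensus position.  The invariant GT/AG dinucleotide
## at the intron ends is never mutated.

DONOR_R <- c("A", "G")

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: a two-genotype
#' design (wildtype vs mutant) with three biological replicates per
#' condition, events drawn over all seven alternative-splicing classes with
#' alternative 3' splice sites and retained introns prominent, moderate
#' effect sizes on the PSI scale and small replicate noise.
#'
#' @param n_genes Number of genes; each hosts exactly one event.
#' @param event_mix Named proportions over SE/RI/A5/A3/MX/AF/AL; must sum
#'   to 1.
#' @param n_replicates Replicates per condition (default 3).
#' @param true_delta_psi Absolute PSI effect size for affected events (sign
#'   is randomised per event).
#' @param fraction_affected Proportion of events with a nonzero effect.
#' @param psi_noise_sd Replicate noise SD on the PSI scale (truncated at
#'   0 and 1).  No empirical estimate is available for this quantity; 0.05
#'   is a package default.
#' @param strong_site_fraction Probability that any one splice site is
#'   generated "strong" (consensus at all key positions).
#' @param depth_scale Median total TPM per event (lognormal, sdlog 0.3).
#' @param periodic_fraction Fraction of A5/A3 boundary shifts that are
#'   multiples of 3 nt (the in-frame periodicity seen for 3'SS shifts).
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 200L,
                       event_mix = c(SE = 0.15, RI = 0.25, A5 = 0.15,
                                     A3 = 0.19, MX = 0.06, AF = 0.12,
                                     AL = 0.08),
                       n_replicates = 3L,
                       true_delta_psi = 0.3,
                       fraction_affected = 0.25,
                       psi_noise_sd = 0.05,
                       strong_site_fraction = 0.5,
                       depth_scale = 50,
                       periodic_fraction = 0.7,
                       seed = 1L) {
  if (!all(names(event_mix) %in% EVENT_CLASSES))
    stop("event_mix names must be among: ", paste(EVENT_CLASSES, collapse = ", "))
  if (any(event_mix < 0) || abs(sum(event_mix) - 1) > 1e-6)
    stop("event_mix proportions must be non-negative and sum to 1")
  if (fraction_affected < 0 || fraction_affected > 1)
    stop("fraction_affected must be in [0, 1]")
  if (psi_noise_sd < 0) stop("psi_noise_sd must be >= 0")
  if (true_delta_psi <= 0 || true_delta_psi > 0.9)
    stop("true_delta_psi must be in (0, 0.9]")
  if (n_genes < 1) stop("n_genes must be >= 1")
  structure(list(n_genes = as.integer(n_genes), event_mix = event_mix,
                 n_replicates = as.integer(n_replicates),
                 true_delta_psi = true_delta_psi,
                 fraction_affected = fraction_affected,
                 psi_noise_sd = psi_noise_sd,
                 strong_site_fraction = strong_site_fraction,
                 depth_scale = depth_scale,
                 periodic_fraction = periodic_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

rlen <- function(lo, hi) sample(seq.int(lo, hi), 1L)

## deviate at 1-3 of the key positions; `alt` lists the allowed
## non-consensus bases per key position
weaken <- function(x, keys, alt) {
  k <- sample(seq_along(keys), sample(1:3, 1L))
  for (i in k) {
    a <- alt[[i]]
    x[keys[i]] <- if (length(a) == 1L) a else sample(a, 1L)
  }
  x
}

## b = sense position of the last exonic base before the intron
stamp_donor <- function(x, b, strong) {
  x[b - 1L] <- "A"; x[b] <- "G"
  x[b + 1L] <- "G"; x[b + 2L] <- "T"
  x[b + 3L] <- sample(DONOR_R, 1L); x[b + 4L] <- "A"; x[b + 5L] <- "G"
  if (!strong)
    x <- weaken(x, c(b - 1L, b, b + 3L, b + 4L, b + 5L),
                list(c("C", "G", "T"), c("A", "C", "T"), c("C", "T"),
                     c("C", "G", "T"), c("A", "C", "T")))
  x
}

## b = sense position of the first exonic base after the intron
stamp_acceptor <- function(x, b, strong) {
  x[(b - 6L):(b - 1L)] <- c("T", "T", "T", "C", "A", "G")
  x[b] <- sample(DONOR_R, 1L)
  if (!strong)
    x <- weaken(x, c(b - 6L, b - 5L, b - 4L, b - 3L, b),
                list(c("A", "C", "G"), c("A", "C", "G"), c("A", "C", "G"),
                     c("A", "G", "T"), c("C", "T")))
  x
}

## Per-class gene layouts, all in sense coordinates.  Each builder returns
## exon intervals per isoform (t1 = inclusion, t2 = exclusion), the donor
## and acceptor boundary positions with a role label, and the event
## coordinate tuple (sense, transcript order).
layout_gene <- function(event_class, periodic_fraction) {
  shift_dist <- function() {
    if (runif(1) < periodic_fraction) sample(c(12L, 15L, 18L, 21L), 1L)
    else sample(c(10L, 11L, 13L, 14L, 16L, 17L, 19L, 20L), 1L)
  }
  switch(event_class,
    SE = {
      a1 <- rlen(90, 150); i1 <- rlen(47, 80); a2 <- rlen(24, 90)
      i2 <- rlen(47, 80); a3 <- rlen(90, 150)
      p2 <- a1 + i1 + 1L; q2 <- a1 + i1 + a2; p3 <- q2 + i2 + 1L
      L <- q2 + i2 + a3
      list(len = L,
           t1 = rbind(c(1L, a1), c(p2, q2), c(p3, L)),
           t2 = rbind(c(1L, a1), c(p3, L)),
           donors = data.frame(pos = c(a1, q2),
                               role = c("upstream-flank", "canonical")),
           acceptors = data.frame(pos = c(p2, p3),
                                  role = c("canonical", "downstream-flank")),
           coords = c(a1, p2, q2, p3))
    },
    RI = {
      a1 <- rlen(90, 150); i1 <- rlen(45, 120); a2 <- rlen(90, 150)
      p2 <- a1 + i1 + 1L; L <- a1 + i1 + a2
      list(len = L,
           t1 = rbind(c(1L, L)),                 # intron retained
           t2 = rbind(c(1L, a1), c(p2, L)),      # intron spliced
           donors = data.frame(pos = a1, role = "canonical"),
           acceptors = data.frame(pos = p2, role = "canonical"),
           coords = c(1L, a1, p2, L))
    },
    A5 = {
      a <- rlen(90, 150); d <- shift_dist(); i1 <- rlen(47, 80)
      e2 <- rlen(90, 150)
      v_up <- a; v_dn <- a + d; anchor <- a + d + i1 + 1L
      L <- a + d + i1 + e2
      ## variant 1 (inclusion) is chosen at random between the two donors
      first_up <- runif(1) < 0.5
      v1 <- if (first_up) v_up else v_dn
      v2 <- if (first_up) v_dn else v_up
      list(len = L,
           t1 = rbind(c(1L, v1), c(anchor, L)),
           t2 = rbind(c(1L, v2), c(anchor, L)),
           donors = data.frame(pos = c(v1, v2), role = c("variant1", "variant2")),
           acceptors = data.frame(pos = anchor, role = "anchor"),
           coords = c(v1, v2, anchor))
    },
    A3 = {
      a <- rlen(90, 150); i1 <- rlen(47, 80); d <- shift_dist()
      e2 <- rlen(90, 150)
      v_up <- a + i1 + 1L; v_dn <- a + i1 + d + 1L
      L <- a + i1 + d + e2
      first_up <- runif(1) < 0.5
      v1 <- if (first_up) v_up else v_dn
      v2 <- if (first_up) v_dn else v_up
      list(len = L,
           t1 = rbind(c(1L, a), c(v1, L)),
           t2 = rbind(c(1L, a), c(v2, L)),
           donors = data.frame(pos = a, role = "anchor"),
           acceptors = data.frame(pos = c(v1, v2), role = c("variant1", "variant2")),
           coords = c(v1, v2, a))
    },
    MX = {
      a1 <- rlen(90, 150); i1 <- rlen(47, 80); ea <- rlen(45, 90)
      i2 <- rlen(47, 80); eb <- rlen(45, 90); i3 <- rlen(47, 80)
      e4 <- rlen(90, 150)
      as_ <- a1 + i1 + 1L; ae <- a1 + i1 + ea
      bs <- ae + i2 + 1L; be <- ae + i2 + eb
      fs <- be + i3 + 1L; L <- be + i3 + e4
      list(len = L,
           t1 = rbind(c(1L, a1), c(as_, ae), c(fs, L)),
           t2 = rbind(c(1L, a1), c(bs, be), c(fs, L)),
           donors = data.frame(pos = c(a1, ae, be),
                               role = c("upstream-flank", "variant1", "variant2")),
           acceptors = data.frame(pos = c(as_, bs, fs),
                                  role = c("variant1", "variant2",
                                           "downstream-flank")),
           coords = c(a1, as_, ae, bs, be, fs))
    },
    AF = {
      x1 <- rlen(60, 120); g1 <- rlen(47, 80); x2 <- rlen(60, 120)
      g2 <- rlen(47, 80); e2 <- rlen(90, 150)
      x2s <- x1 + g1 + 1L; x2e <- x1 + g1 + x2
      anchor <- x2e + g2 + 1L; L <- x2e + g2 + e2
      list(len = L,
           t1 = rbind(c(1L, x1), c(anchor, L)),
           t2 = rbind(c(x2s, x2e), c(anchor, L)),
           donors = data.frame(pos = c(x1, x2e), role = c("variant1", "variant2")),
           acceptors = data.frame(pos = anchor, role = "anchor"),
           coords = c(1L, x1, x2s, x2e, anchor))
    },
    AL = {
      e1 <- rlen(90, 150); g1 <- rlen(47, 80); y1 <- rlen(60, 120)
      g2 <- rlen(47, 80); y2 <- rlen(60, 120)
      y1s <- e1 + g1 + 1L; y1e <- e1 + g1 + y1
      y2s <- y1e + g2 + 1L; L <- y1e + g2 + y2
      list(len = L,
           t1 = rbind(c(1L, e1), c(y1s, y1e)),
           t2 = rbind(c(1L, e1), c(y2s, L)),
           donors = data.frame(pos = e1, role = "anchor"),
           acceptors = data.frame(pos = c(y1s, y2s),
                                  role = c("variant1", "variant2")),
           coords = c(e1, y1s, y1e, y2s, L))
    },
    stop("unknown event class: ", event_class))
}

#' Simulate a toy genome, annotation, events and splicing truth table
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` ([Biostrings::DNAStringSet]),
#'   `annotation` ([tx_annotation()]), `events` ([splice_events()]) and
#'   `truth` (list of data frames `events` — per-event PSI truth — and
#'   `sites` — per-splice-site strength labels with genomic boundary
#'   coordinates).
#' @export
simulate_genome_and_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  mix <- config$event_mix
  classes <- if (length(mix) == 1L) rep(names(mix), n) else
    sample(names(mix), n, replace = TRUE, prob = mix)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  affected <- runif(n) < config$fraction_affected
  delta <- config$true_delta_psi

  genes_per_contig <- 25L
  spacer <- 100L
  contig_of <- paste0("chr", (seq_len(n) - 1L) %/% genes_per_contig + 1L)
  gene_ids <- sprintf("g%04d", seq_len(n))

  contig_parts <- list()
  offset <- setNames(rep(0L, length(unique(contig_of))), unique(contig_of))
  ann_rows <- vector("list", n)
  ev_rows <- vector("list", n)
  truth_ev <- vector("list", n)
  truth_sites <- vector("list", n)

  for (i in seq_len(n)) {
    cls <- classes[i]; std <- strands[i]; ctg <- contig_of[i]
    lay <- layout_gene(cls, config$periodic_fraction)
    L <- lay$len
    x <- rand_bases(L)
    sites <- rbind(
      data.frame(kind = "donor", pos = lay$donors$pos,
                 role = lay$donors$role, stringsAsFactors = FALSE),
      data.frame(kind = "acceptor", pos = lay$acceptors$pos,
                 role = lay$acceptors$role, stringsAsFactors = FALSE))
    sites$strong <- runif(nrow(sites)) < config$strong_site_fraction
    for (j in seq_len(nrow(sites)))
      x <- if (sites$kind[j] == "donor")
        stamp_donor(x, sites$pos[j], sites$strong[j])
      else stamp_acceptor(x, sites$pos[j], sites$strong[j])

    ## place on the contig: spacer, then the gene (reverse-complemented for
    ## minus-strand genes)
    O <- offset[ctg] + spacer
    sense <- paste(x, collapse = "")
    placed <- if (std == "+") sense else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
    contig_parts[[length(contig_parts) + 1L]] <-
      list(contig = ctg, seq = paste0(strrep("", 0),
                                      paste(rand_bases(spacer), collapse = ""),
                                      placed))
    offset[ctg] <- O + L

    map_pos <- function(s) if (std == "+") O + s else O + L + 1L - s
    map_exons <- function(m) {
      g <- cbind(map_pos(m[, 1]), map_pos(m[, 2]))
      t(apply(g, 1L, sort))
    }

    gid <- gene_ids[i]
    tx1 <- paste0(gid, ".t1"); tx2 <- paste0(gid, ".t2")
    ex1 <- map_exons(lay$t1); ex2 <- map_exons(lay$t2)
    ann_rows[[i]] <- data.frame(
      gene_id = gid,
      transcript_id = rep(c(tx1, tx2), c(nrow(ex1), nrow(ex2))),
      contig = ctg, strand = std,
      start = c(ex1[, 1], ex2[, 1]), end = c(ex1[, 2], ex2[, 2]),
      stringsAsFactors = FALSE)

    gco <- as.integer(vapply(lay$coords, map_pos, numeric(1)))
    eid <- format_event_id(gid, cls, ctg, std, gco)
    ev_rows[[i]] <- data.frame(event_id = eid, gene_id = gid,
                               event_class = cls, contig = ctg, strand = std,
                               stringsAsFactors = FALSE)
    ev_rows[[i]]$coords <- list(gco)
    ev_rows[[i]]$inclusion <- list(tx1)
    ev_rows[[i]]$total <- list(c(tx1, tx2))

    if (affected[i]) {
      sgn <- sample(c(-1, 1), 1L)
      psi_wt <- if (sgn > 0) runif(1, 0.05, 0.95 - delta)
                else runif(1, 0.05 + delta, 0.95)
      psi_mut <- psi_wt + sgn * delta
    } else {
      psi_wt <- psi_mut <- runif(1, 0.1, 0.9)
    }
    truth_ev[[i]] <- data.frame(
      event_id = eid, gene_id = gid, event_class = cls,
      psi_wildtype = psi_wt, psi_mutant = psi_mut,
      true_delta_psi = psi_mut - psi_wt, affected = affected[i],
      inclusion_tx = tx1, exclusion_tx = tx2, stringsAsFactors = FALSE)
    truth_sites[[i]] <- data.frame(
      event_id = eid, contig = ctg, strand = std,
      site_kind = sites$kind, role = sites$role,
      boundary = vapply(sites$pos, map_pos, numeric(1)),
      strength = ifelse(sites$strong, "strong", "weak"),
      stringsAsFactors = FALSE)
  }

  ## assemble contigs (terminal spacer appended)
  ctg_names <- unique(contig_of)
  seqs <- vapply(ctg_names, function(ctg) {
    parts <- Filter(function(p) p$contig == ctg, contig_parts)
    paste0(paste(vapply(parts, `[[`, "", "seq"), collapse = ""),
           paste(rand_bases(spacer), collapse = ""))
  }, character(1))
  genome <- Biostrings::DNAStringSet(setNames(seqs, ctg_names))

  annotation <- tx_annotation(do.call(rbind, ann_rows))
  events <- splice_events(do.call(rbind, ev_rows))
  truth <- list(events = do.call(rbind, truth_ev),
                sites = do.call(rbind, truth_sites))
  rownames(truth$events) <- rownames(truth$sites) <- NULL
  list(genome = genome, annotation = annotation, events = events,
       truth = truth)
}

#' Simulate replicate abundance matrices from a splicing truth table
#'
#' For every event and sample the realised PSI is the condition's true PSI
#' plus truncated-Gaussian noise; the event's total TPM is lognormal around
#' `depth_scale` and is split between the inclusion and exclusion isoform
#' in proportion to the realised PSI.
#'
#' @param truth Truth list from [simulate_genome_and_events()] (its
#'   `events` component is used).
#' @param config The same [sim_config()].
#' @return List with `tpm` (transcripts x samples matrix) and `design`
#'   (sample/condition data frame).
#' @export
simulate_abundances <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_replicates < 2L)
    stop("n_replicates must be >= 2 for downstream testing")
  te <- truth$events
  set.seed(config$seed + 1L)
  conds <- c("wildtype", "mutant")
  design <- data.frame(
    sample_id = paste0(rep(conds, each = config$n_replicates), "_",
                       rep(seq_len(config$n_replicates), 2L)),
    condition = rep(conds, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), 2L),
    stringsAsFactors = FALSE)
  ns <- nrow(design)
  ne <- nrow(te)
  true_psi <- ifelse(rep(design$condition, each = ne) == "wildtype",
                     te$psi_wildtype, te$psi_mutant)
  psi <- matrix(pmin(1, pmax(0, true_psi +
                               rnorm(ne * ns, 0, config$psi_noise_sd))),
                nrow = ne)
  total <- matrix(rlnorm(ne * ns, meanlog = log(config$depth_scale),
                         sdlog = 0.3), nrow = ne)
  tpm <- matrix(0, nrow = 2L * ne, ncol = ns,
                dimnames = list(c(rbind(te$inclusion_tx, te$exclusion_tx)),
                                design$sample_id))
  tpm[te$inclusion_tx, ] <- psi * total
  tpm[te$exclusion_tx, ] <- (1 - psi) * total
  list(tpm = tpm, design = design)
}

#' Simulate a complete dataset (genome, annotation, events, abundances)
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `annotation`, `events`, `truth`, `tpm`,
#'   `design`.
#' @export
simulate_splicing_dataset <- function(config = sim_config()) {
  sim <- simulate_genome_and_events(config)
  ab <- simulate_abundances(sim$truth, config)
  c(sim, ab)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' @param sim Result of [simulate_splicing_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gtf"),
             events = file.path(dir, "events.ioe"),
             tpm = file.path(dir, "tpm.tsv"),
             design = file.path(dir, "design.tsv"),
             truth_events = file.path(dir, "truth_events.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_gtf(sim$annotation, paths["annotation"])
  write_ioe(sim$events, paths["events"])
  write_tpm(sim$tpm, paths["tpm"])
  write.table(sim$design, paths["design"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$events, paths["truth_events"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$sites, paths["truth_sites"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
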