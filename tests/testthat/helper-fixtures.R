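# Shared fixtures: a small simulated dataset reused across test files, and
# hand-built micro-objects for exact-value tests.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_splicing_dataset(sim_config(n_genes = 60, seed = 42))
    cache
  }
})

# full-size dataset at the standard recovery conditions (200 events, 25%
# affected, |dPSI| 0.3, noise sd 0.05, 3 + 3 replicates, depth 50)
recovery_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_splicing_dataset(sim_config(n_genes = 200, seed = 42))
    cache
  }
})

# two-exon plus-strand annotation on a 600 bp contig
toy_annotation <- function() {
  tx_annotation(data.frame(
    gene_id = "g1", transcript_id = c("t1", "t1"),
    contig = "chr1", strand = "+",
    start = c(101, 301), end = c(200, 400)))
}

# genome with a donor CAG|GTAAGT stamped at exon end 100 (plus strand) and
# its reverse complement planted on a second contig
toy_genome_with_donor <- function() {
  set.seed(5)
  x <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  x[98:106] <- strsplit("CAGGTAAGT", "")[[1]]
  fwd <- paste(x, collapse = "")
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  Biostrings::DNAStringSet(c(chrF = fwd, chrR = rev))
}

make_events <- function(event_id, gene_id, event_class, contig, strand,
                        coords, inclusion, total) {
  ev <- data.frame(event_id = event_id, gene_id = gene_id,
                   event_class = event_class, contig = contig,
                   strand = strand, stringsAsFactors = FALSE)
  ev$coords <- coords
  ev$inclusion <- inclusion
  ev$total <- total
  splice_events(ev)
}

# truth-vs-call confusion helper
recovery_rates <- function(ds, truth_events) {
  tru <- truth_events$affected[match(ds$event_id, truth_events$event_id)]
  list(sensitivity = sum(ds$significant & tru) / sum(tru),
       fdp = if (sum(ds$significant) == 0) 0
             else sum(ds$significant & !tru) / sum(ds$significant))
}
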