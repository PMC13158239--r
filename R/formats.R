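## Readers/writers for the external formats the pipeline touches, plus the
## lightweight S3 containers used throughout.  All coordinates handled here
## are 1-based inclusive (GTF/ioe native); event coordinate tuples are kept
## in transcript order (values decrease along the tuple on the minus strand).

EVENT_CLASSES <- c("SE", "RI", "A5", "A3", "MX", "AF", "AL")

## arity of the coordinate tuple per event class
EVENT_COORD_ARITY <- c(SE = 4L, RI = 4L, A5 = 3L, A3 = 3L,
                       MX = 6L, AF = 5L, AL = 5L)

# ---------------------------------------------------------------------------
# genome sequences

#' Read a genome FASTA file
#'
#' Sequences are uppercased on load so that all downstream sequence
#' comparisons are case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique contig names.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write genome sequences to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# transcript annotation

#' Construct a transcript annotation table
#'
#' The annotation is a data frame of exons with columns `gene_id`,
#' `transcript_id`, `contig`, `strand`, `start`, `end` (1-based inclusive),
#' sorted by transcript and genomic position.  Introns are the gaps between
#' consecutive exons of a transcript.
#'
#' @param exons Data frame with the columns above.
#' @return The validated annotation, classed `"tx_annotation"`.
#' @export
tx_annotation <- function(exons) {
  need <- c("gene_id", "transcript_id", "contig", "strand", "start", "end")
  if (!all(need %in% names(exons)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  exons <- as.data.frame(exons)[, need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end < exons$start)) stop("exon end < start")
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ns <- tapply(exons$strand, exons$transcript_id, function(s) length(unique(s)))
  if (any(ns > 1))
    stop("mixed strands within transcript(s): ",
         paste(names(ns)[ns > 1], collapse = ", "))
  exons <- exons[order(exons$transcript_id, exons$start), ]
  ok <- tapply(seq_len(nrow(exons)), exons$transcript_id, function(i) {
    s <- exons$start[i]; e <- exons$end[i]
    length(i) == 1L || all(s[-1] > e[-length(e)])
  })
  if (!all(unlist(ok)))
    stop("overlapping exons within transcript(s): ",
         paste(names(ok)[!unlist(ok)], collapse = ", "))
  rownames(exons) <- NULL
  class(exons) <- c("tx_annotation", "data.frame")
  exons
}

#' Read transcript annotation from GTF
#'
#' Keeps `exon` features and groups them per transcript; coordinates stay
#' 1-based inclusive.
#'
#' @param path Path to a GTF file with `gene_id`/`transcript_id` attributes.
#' @return A [tx_annotation()] data frame.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("exon feature(s) missing transcript_id attribute")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon feature(s) missing gene_id attribute")
  tx_annotation(data.frame(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Write transcript annotation to GTF
#'
#' @param annotation A [tx_annotation()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = "exon",
    source = "spliceflow",
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Intron intervals of every transcript
#'
#' @param annotation A [tx_annotation()] data frame.
#' @return Data frame with `gene_id`, `transcript_id`, `contig`, `strand`,
#'   `start`, `end` (1-based inclusive intron intervals).
#' @export
tx_introns <- function(annotation) {
  sp <- split(seq_len(nrow(annotation)), annotation$transcript_id)
  out <- lapply(sp, function(i) {
    if (length(i) < 2L) return(NULL)
    s <- annotation$start[i]; e <- annotation$end[i]
    data.frame(gene_id = annotation$gene_id[i[1]],
               transcript_id = annotation$transcript_id[i[1]],
               contig = annotation$contig[i[1]],
               strand = annotation$strand[i[1]],
               start = e[-length(e)] + 1L,
               end = s[-1] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      contig = character(), strand = character(),
                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}

#' Spliced (mature) transcript lengths
#'
#' @param annotation A [tx_annotation()] data frame.
#' @return Named integer vector of summed exon lengths per transcript.
#' @export
tx_lengths <- function(annotation) {
  len <- tapply(annotation$end - annotation$start + 1L,
                annotation$transcript_id, sum)
  setNames(as.integer(len), names(len))
}

# ---------------------------------------------------------------------------
# splice events (ioe dialect)

#' Construct a splice-event table
#'
#' @param events Data frame with columns `event_id`, `gene_id`,
#'   `event_class`, `contig`, `strand`, and list columns `coords`
#'   (class-specific integer tuple, transcript order), `inclusion`
#'   and `total` (transcript id sets).
#' @return The validated table, classed `"splice_events"`.
#' @export
splice_events <- function(events) {
  need <- c("event_id", "gene_id", "event_class", "contig", "strand",
            "coords", "inclusion", "total")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  events <- as.data.frame(events)[, need]
  if (!all(events$event_class %in% EVENT_CLASSES))
    stop("unknown event class: ",
         paste(setdiff(events$event_class, EVENT_CLASSES), collapse = ", "))
  arity <- EVENT_COORD_ARITY[events$event_class]
  got <- vapply(events$coords, length, integer(1))
  if (any(got != arity))
    stop("coordinate tuple arity mismatch for event(s): ",
         paste(events$event_id[got != arity], collapse = ", "))
  for (i in seq_len(nrow(events))) {
    inc <- events$inclusion[[i]]; tot <- events$total[[i]]
    if (length(inc) == 0L || length(tot) == 0L)
      stop("empty transcript set in event ", events$event_id[i])
    if (!all(inc %in% tot))
      stop("inclusion transcripts not a subset of total in event ",
           events$event_id[i])
    if (length(setdiff(tot, inc)) == 0L)
      stop("event ", events$event_id[i],
           " has no exclusion transcripts (inclusion == total)")
  }
  rownames(events) <- NULL
  class(events) <- c("splice_events", "data.frame")
  events
}

#' Serialise an event to its ioe event_id string
#'
#' The event_id grammar, all coordinates 1-based genomic in transcript
#' order:
#' \preformatted{
#'   SE: gene;SE:chr:e1end-e2start:e2end-e3start:strand
#'   RI: gene;RI:chr:e1start:e1end-e2start:e2end:strand
#'   A5/A3: gene;A5:chr:v1-anchor:v2-anchor:strand
#'   MX: gene;MX:chr:e1end-astart:aend-e4start:e1end-bstart:bend-e4start:strand
#'   AF: gene;AF:chr:x1start:x1end-anchor:x2start:x2end-anchor:strand
#'   AL: gene;AL:chr:anchor-y1start:y1end:anchor-y2start:y2end:strand
#' }
#'
#' @param gene_id,event_class,contig,strand Event fields.
#' @param coords Class-specific integer coordinate tuple.
#' @return The event_id string.
#' @export
format_event_id <- function(gene_id, event_class, contig, strand, coords) {
  co <- as.integer(coords)
  seg <- switch(event_class,
    SE = c(paste0(co[1], "-", co[2]), paste0(co[3], "-", co[4])),
    RI = c(co[1], paste0(co[2], "-", co[3]), co[4]),
    A5 = ,
    A3 = c(paste0(co[1], "-", co[3]), paste0(co[2], "-", co[3])),
    MX = c(paste0(co[1], "-", co[2]), paste0(co[3], "-", co[6]),
           paste0(co[1], "-", co[4]), paste0(co[5], "-", co[6])),
    AF = c(co[1], paste0(co[2], "-", co[5]), co[3],
           paste0(co[4], "-", co[5])),
    AL = c(paste0(co[1], "-", co[2]), co[3], paste0(co[1], "-", co[4]),
           co[5]),
    stop("unknown event class: ", event_class))
  paste0(gene_id, ";", event_class, ":", contig, ":",
         paste(seg, collapse = ":"), ":", strand)
}

#' Parse an ioe event_id string
#'
#' Inverse of [format_event_id()]; validates the class code, strand,
#' segment arities and shared-anchor consistency.
#'
#' @param event_id An event_id string.
#' @return List with `gene_id`, `event_class`, `contig`, `strand`,
#'   `coords`.
#' @export
parse_event_id <- function(event_id) {
  halves <- strsplit(event_id, ";", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("malformed event_id: ", event_id)
  gene_id <- halves[1]
  fields <- strsplit(halves[2], ":", fixed = TRUE)[[1]]
  if (length(fields) < 4L) stop("malformed event_id: ", event_id)
  cls <- fields[1]
  if (!cls %in% EVENT_CLASSES)
    stop("unknown event class code '", cls, "' in event_id: ", event_id)
  contig <- fields[2]
  strand <- fields[length(fields)]
  if (!strand %in% c("+", "-")) stop("malformed strand in event_id: ", event_id)
  seg <- fields[3:(length(fields) - 1L)]
  part <- lapply(strsplit(seg, "-", fixed = TRUE), function(x) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) stop("non-numeric coordinate in event_id: ", event_id)
    v
  })
  nseg <- vapply(part, length, integer(1))
  coords <- switch(cls,
    SE = { stopifnot(length(seg) == 2L, all(nseg == 2L))
           c(part[[1]], part[[2]]) },
    RI = { stopifnot(length(seg) == 3L, all(nseg == c(1L, 2L, 1L)))
           c(part[[1]], part[[2]], part[[3]]) },
    A5 = ,
    A3 = { stopifnot(length(seg) == 2L, all(nseg == 2L))
           if (part[[1]][2] != part[[2]][2])
             stop("variant boundaries do not share an anchor in event_id: ",
                  event_id)
           c(part[[1]][1], part[[2]][1], part[[1]][2]) },
    MX = { stopifnot(length(seg) == 4L, all(nseg == 2L))
           if (part[[1]][1] != part[[3]][1] || part[[2]][2] != part[[4]][2])
             stop("inconsistent flanking coordinates in MX event_id: ",
                  event_id)
           c(part[[1]][1], part[[1]][2], part[[2]][1], part[[3]][2],
             part[[4]][1], part[[2]][2]) },
    AF = { stopifnot(length(seg) == 4L, all(nseg == c(1L, 2L, 1L, 2L)))
           if (part[[2]][2] != part[[4]][2])
             stop("AF variants do not share an anchor in event_id: ", event_id)
           c(part[[1]], part[[2]][1], part[[3]], part[[4]][1], part[[2]][2]) },
    AL = { stopifnot(length(seg) == 4L, all(nseg == c(2L, 1L, 2L, 1L)))
           if (part[[1]][1] != part[[3]][1])
             stop("AL variants do not share an anchor in event_id: ", event_id)
           c(part[[1]][1], part[[1]][2], part[[2]], part[[3]][2], part[[4]]) })
  list(gene_id = gene_id, event_class = cls, contig = contig,
       strand = strand, coords = as.integer(coords))
}

#' Read splice-event definitions (ioe dialect)
#'
#' Tab-separated with header
#' `seqname gene_id event_id alternative_transcripts total_transcripts`;
#' transcript sets are comma-separated; all coordinates in `event_id`
#' are 1-based genomic, written in transcript order.
#'
#' @param path Path to an ioe file.
#' @return A [splice_events()] data frame.
#' @export
read_ioe <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seqname", "gene_id", "event_id", "alternative_transcripts",
            "total_transcripts")
  if (!all(need %in% names(tab)))
    stop("ioe file must have header: ", paste(need, collapse = " "))
  parsed <- lapply(tab$event_id, parse_event_id)
  ev <- data.frame(
    event_id = tab$event_id,
    gene_id = vapply(parsed, `[[`, "", "gene_id"),
    event_class = vapply(parsed, `[[`, "", "event_class"),
    contig = vapply(parsed, `[[`, "", "contig"),
    strand = vapply(parsed, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  if (!identical(ev$contig, tab$seqname))
    stop("seqname column disagrees with event_id contig")
  ev$coords <- lapply(parsed, `[[`, "coords")
  ev$inclusion <- strsplit(tab$alternative_transcripts, ",", fixed = TRUE)
  ev$total <- strsplit(tab$total_transcripts, ",", fixed = TRUE)
  splice_events(ev)
}

#' Write splice-event definitions (ioe dialect)
#'
#' @param events A [splice_events()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ioe <- function(events, path) {
  tab <- data.frame(
    seqname = events$contig,
    gene_id = events$gene_id,
    event_id = events$event_id,
    alternative_transcripts =
      vapply(events$inclusion, paste, "", collapse = ","),
    total_transcripts = vapply(events$total, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# abundance, design and generic tables

#' Read a transcript abundance (TPM) table
#'
#' @param path TSV with a `transcript_id` column and one numeric column per
#'   sample.
#' @return Numeric matrix, transcripts x samples.
#' @export
read_tpm <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"transcript_id" %in% names(tab))
    stop("TPM table must have a transcript_id column")
  m <- as.matrix(tab[, setdiff(names(tab), "transcript_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$transcript_id
  if (anyNA(m)) stop("missing TPM values")
  if (any(m < 0)) stop("negative TPM values")
  m
}

#' Write a transcript abundance (TPM) table
#'
#' @param tpm Numeric matrix, transcripts x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm <- function(tpm, path) {
  tab <- data.frame(transcript_id = rownames(tpm), tpm, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample/condition design table
#'
#' @param path TSV with columns `sample_id`, `condition`, `replicate`.
#' @return Data frame; a warning is raised (and `attr(,"underpowered")` set)
#'   when any condition has fewer than two samples — testing operations
#'   refuse such designs.
#' @export
read_design <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(tab)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in design")
  n <- table(tab$condition)
  attr(tab, "underpowered") <- any(n < 2L)
  if (any(n < 2L))
    warning("condition(s) with a single sample: ",
            paste(names(n)[n < 2L], collapse = ", "))
  tab
}

#' Write a data frame as a TSV result table
#'
#' List columns (coordinate tuples, transcript sets) are flattened to
#' comma-separated strings.  An optional header comment records the
#' generating parameters so result tables are auditable.
#'
#' @param records Data frame.
#' @param path Output path.
#' @param comment Optional character vector written as `# `-prefixed header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, comment = NULL) {
  records <- as.data.frame(records)
  for (j in seq_along(records))
    if (is.list(records[[j]]))
      records[[j]] <- vapply(records[[j]], paste, "", collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table written by [write_table()]
#'
#' @param path Input path.
#' @return Data frame (header comments skipped).
#' @export
read_table_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
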