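#' Read and write FASTA sequences
#'
#' Thin wrappers over Biostrings; sequences travel as named character
#' vectors inside the package.
#'
#' @param x named character vector of sequences (or a `synthetic_genome`).
#' @param file path to a FASTA file.
#' @return `read_fasta()` returns a named character vector;
#'   `write_fasta()` returns `file` invisibly.
#' @export
write_fasta <- function(x, file) {
  if (inherits(x, "synthetic_genome")) x <- unlist(genome_sequences(x))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  s <- Biostrings::readDNAStringSet(file)
  setNames(as.character(s), names(s))
}

#' Export transcript models as GTF
#'
#' Emits one `exon` feature per exon with `gene_id`/`transcript_id`
#' attributes via rtracklayer (1-based closed coordinates, the GTF
#' convention, which is also the package's internal one).
#'
#' @param models list of [transcript_model()] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(models, file) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GTF export")
  }
  tab <- models_to_exon_table(models)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$contig,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand,
    type = "exon", gene_id = tab$gene_id, transcript_id = tab$transcript_id
  )
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Import transcript models from GTF/GFF
#'
#' Reads exon features and reassembles one [transcript_model()] per
#' transcript id.
#'
#' @param file GTF/GFF path.
#' @return named list of [transcript_model()] objects.
#' @export
read_gtf <- function(file) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GTF import")
  }
  gr <- rtracklayer::import(file)
  gr <- gr[gr$type == "exon"]
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    transcript_id = gr$transcript_id, gene_id = gr$gene_id
  )
  lapply(split(df, df$transcript_id), function(s) {
    transcript_model(s$transcript_id[1], s$contig[1], s$strand[1],
                     s$start, s$end, gene_id = s$gene_id[1])
  })
}

#' Import a transcript alignment table from SAM/BAM
#'
#' Extracts, per alignment record, the contig, strand, span, aligned
#' length and the NM-style edit count into the package's alignment table
#' layout (secondary/supplementary records become extra segment rows of
#' their read).
#'
#' @param file SAM or BAM path (SAM files are converted on the fly).
#' @return a [transcript_alignments()] table.
#' @export
read_alignments_sam <- function(file) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for SAM/BAM import")
  }
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "qwidth", "cigar"),
    tag = "NM"
  )
  b <- Rsamtools::scanBam(file, param = p)[[1]]
  keep <- !is.na(b$pos)
  ref_w <- GenomicAlignments_width(b$cigar[keep])
  aln_w <- cigar_aligned_length(b$cigar[keep])
  df <- data.frame(
    read_id = b$qname[keep],
    contig = as.character(b$rname[keep]),
    strand = as.character(b$strand[keep]),
    start = b$pos[keep],
    end = b$pos[keep] + ref_w - 1L,
    read_len = b$qwidth[keep],
    L = aln_w,
    K = b$tag$NM[keep] %||% rep(0L, sum(keep))
  )
  df$K[is.na(df$K)] <- 0L
  segs <- stats::ave(seq_len(nrow(df)), df$read_id, FUN = seq_along)
  df$segment <- segs
  transcript_alignments(df)
}

## reference span consumed by a CIGAR (M/D/N/=/X)
GenomicAlignments_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## aligned length: matched bases plus indel bases (M/I/D/=/X)
cigar_aligned_length <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "I", "D", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write the planted-truth sidecar as JSON
#'
#' @param sim result of [simulate_long_reads()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_truth_json <- function(sim, file) {
  jsonlite::write_json(
    list(truth = sim$truth, fusion_truth = sim$fusion_truth),
    file, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}
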