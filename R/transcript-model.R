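#' Strand-aware exon-chain transcript model
#'
#' The universal currency of the package: an ordered chain of exons on one
#' contig and strand. Isoforms, long reads as aligned, and reference
#' annotation entries are all represented this way. Coordinates are 1-based
#' and closed, the convention of GTF and of R/Bioconductor interval tools.
#'
#' @param id transcript identifier.
#' @param contig contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends integer vectors of exon starts and ends (1-based,
#'   closed, `starts[i] <= ends[i]`). Exons must be disjoint and separated by
#'   at least 1 bp of intron; they are sorted internally.
#' @param gene_id gene the transcript belongs to (defaults to `id`).
#' @param cds optional genomic CDS span `c(start, end)`.
#' @return An object of class `transcript_model`.
#' @examples
#' tm <- transcript_model("t1", "chr1", "+", c(1, 201, 401), c(100, 300, 500))
#' transcript_introns(tm)
#' @export
transcript_model <- function(id, contig, strand, starts, ends,
                             gene_id = id, cds = NULL) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1)
  starts <- as.integer(starts); ends <- as.integer(ends)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(ends < starts)) stop("exon end before exon start in '", id, "'")
  if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)] + 1L)) {
    stop("exons of '", id, "' overlap or abut; introns must be >= 1 bp")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(cds)) {
    stopifnot(length(cds) == 2, cds[1] <= cds[2])
    cds <- as.integer(cds)
  }
  structure(
    list(id = id, gene_id = gene_id, contig = contig, strand = strand,
         exon_start = starts, exon_end = ends, cds = cds),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s] %d exon(s)\n",
              x$id, x$gene_id, x$contig, min(x$exon_start), max(x$exon_end),
              x$strand, length(x$exon_start)))
  invisible(x)
}

#' Derived intron chain of a transcript model
#'
#' @param tm a [transcript_model()].
#' @return data.frame with columns `start`, `end` (1-based closed intron
#'   coordinates); zero rows for single-exon models.
#' @export
transcript_introns <- function(tm) {
  n <- length(tm$exon_start)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = tm$exon_end[-n] + 1L, end = tm$exon_start[-1] - 1L)
}

#' Genomic span, spliced length and junctions
#'
#' `transcript_span()` returns the genomic interval covered,
#' `transcript_spliced_length()` the summed exon length, and
#' `transcript_junctions()` the intron chain keyed for junction matching.
#'
#' @param tm a [transcript_model()].
#' @return see individual descriptions.
#' @export
transcript_span <- function(tm) c(min(tm$exon_start), max(tm$exon_end))

#' @rdname transcript_span
#' @export
transcript_spliced_length <- function(tm) {
  sum(tm$exon_end - tm$exon_start + 1L)
}

#' @rdname transcript_span
#' @export
transcript_junctions <- function(tm) {
  intr <- transcript_introns(tm)
  if (nrow(intr) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  data.frame(contig = tm$contig, start = intr$start, end = intr$end,
             strand = tm$strand)
}

intron_chain_key <- function(tm) {
  intr <- transcript_introns(tm)
  paste(tm$contig, tm$strand,
        paste(intr$start, intr$end, sep = "-", collapse = ","), sep = "|")
}

#' Do two transcript models have identical intron chains?
#'
#' Identity requires the same contig, the same strand and byte-identical
#' ordered intron coordinates; terminal exon ends are free to differ. Two
#' single-exon models on the same contig and strand trivially share the empty
#' chain.
#'
#' @param a,b [transcript_model()] objects.
#' @return logical flag.
#' @export
identical_intron_chain <- function(a, b) {
  intron_chain_key(a) == intron_chain_key(b)
}

## number of shared (exact) splice junctions between two models
n_shared_junctions <- function(a, b) {
  if (a$contig != b$contig || a$strand != b$strand) return(0L)
  ja <- transcript_introns(a); jb <- transcript_introns(b)
  if (nrow(ja) == 0 || nrow(jb) == 0) return(0L)
  sum(paste(ja$start, ja$end) %in% paste(jb$start, jb$end))
}

#' Spliced (mature) sequence of a transcript model
#'
#' Concatenates the exon substrings of the genome and reverse-complements
#' for minus-strand models, giving the 5'-to-3' transcript sequence.
#'
#' @param tm a [transcript_model()].
#' @param genome a [generate_genome()] object (or any named character vector
#'   of contig sequences).
#' @return character scalar DNA sequence.
#' @export
transcript_sequence <- function(tm, genome) {
  seqs <- genome_sequences(genome)
  if (!tm$contig %in% names(seqs)) {
    stop("contig '", tm$contig, "' not present in genome")
  }
  s <- paste(substring(seqs[[tm$contig]], tm$exon_start, tm$exon_end),
             collapse = "")
  if (tm$strand == "-") s <- revcomp(s)
  s
}

#' Convert a list of transcript models to an exon table
#'
#' One row per exon, the layout used for GTF export and quick inspection.
#'
#' @param models list of [transcript_model()] objects.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`, `exon_number`.
#' @export
models_to_exon_table <- function(models) {
  do.call(rbind, lapply(models, function(tm) {
    n <- length(tm$exon_start)
    num <- if (tm$strand == "+") seq_len(n) else rev(seq_len(n))
    data.frame(contig = tm$contig, start = tm$exon_start, end = tm$exon_end,
               strand = tm$strand, transcript_id = tm$id,
               gene_id = tm$gene_id, exon_number = num)
  }))
}
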