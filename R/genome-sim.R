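#' Generate a toy multi-contig genome
#'
#' Draws i.i.d. bases at a target GC content. Structural stand-in for a
#' draft plant assembly made of many ordered contigs; contig names take a
#' configurable prefix so that chromosome-like and scaffold-like sequences
#' can coexist (used by fusion span subtyping).
#'
#' @param n_contigs number of contigs (>= 1).
#' @param contig_length length of each contig in bp (>= 1000), scalar or
#'   vector of length `n_contigs`.
#' @param gc GC fraction in (0, 1). Default 0.46, a typical grass genome
#'   value.
#' @param seed optional integer seed; fixing it makes the genome
#'   bit-reproducible.
#' @param prefix contig name prefix, default `"chr"`.
#' @return An object of class `synthetic_genome`: a named list of contig
#'   sequences with accessor [genome_sequences()].
#' @examples
#' g <- generate_genome(2, 5000, gc = 0.4, seed = 1)
#' nchar(genome_sequences(g)[[1]])
#' @export
generate_genome <- function(n_contigs, contig_length, gc = 0.46, seed = NULL,
                            prefix = "chr") {
  if (n_contigs < 1) stop("n_contigs must be >= 1")
  contig_length <- rep_len(as.integer(contig_length), n_contigs)
  if (any(contig_length < 1000L)) stop("contig_length must be >= 1000 bp")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  maybe_seed(seed)
  seqs <- lapply(contig_length, random_dna, gc = gc)
  names(seqs) <- sprintf("%s%02d", prefix, seq_len(n_contigs))
  structure(list(seqs = seqs), class = "synthetic_genome")
}

#' Contig sequences of a genome object
#'
#' @param genome a `synthetic_genome` or a plain named character vector /
#'   list of sequences.
#' @return named list of character sequences.
#' @export
genome_sequences <- function(genome) {
  if (inherits(genome, "synthetic_genome")) return(genome$seqs)
  as.list(genome)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  len <- vapply(x$seqs, nchar, integer(1))
  cat(sprintf("<synthetic_genome> %d contig(s), %d bp total\n",
              length(len), sum(len)))
  invisible(x)
}

## overwrite genome bases in place (1-based closed)
patch_genome <- function(genome, contig, start, replacement) {
  s <- genome$seqs[[contig]]
  substr(s, start, start + nchar(replacement) - 1L) <- replacement
  genome$seqs[[contig]] <- s
  genome
}

#' Place multi-exon gene models on a synthetic genome
#'
#' Genes are laid out left to right on alternating contigs with random
#' intergenic gaps, on both strands, and never overlap. Canonical splice
#' dinucleotides are written into the genome at every intron boundary:
#' `GT..AG` on the coding strand (so `CT..AC` appears in the plus-strand
#' genome sequence under a minus-strand gene).
#'
#' @param genome a [generate_genome()] object; returned modified.
#' @param n_genes number of genes to place.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_len,intron_len integer ranges for exon and intron lengths (bp).
#' @param intergenic integer range for gaps between neighbouring genes (bp).
#' @param with_cds if `TRUE`, a genomic CDS span is recorded, inset from the
#'   transcript span by `utr` bp on each side.
#' @param utr UTR width used when `with_cds = TRUE`.
#' @param seed optional integer seed.
#' @return list with elements `genome` (patched genome) and `models`
#'   (list of single-isoform [transcript_model()] gene models named by gene
#'   id).
#' @export
generate_gene_models <- function(genome, n_genes,
                                 exons_per_gene = c(3L, 6L),
                                 exon_len = c(80L, 300L),
                                 intron_len = c(60L, 400L),
                                 intergenic = c(500L, 2000L),
                                 with_cds = FALSE, utr = 40L,
                                 seed = NULL) {
  stopifnot(n_genes >= 1, exons_per_gene[1] >= 1,
            exon_len[1] >= 10, intron_len[1] >= 20)
  maybe_seed(seed)
  seqs <- genome_sequences(genome)
  contigs <- names(seqs)
  clen <- vapply(seqs, nchar, integer(1))
  cursor <- setNames(pmax(200L, as.integer(runif(length(contigs), 200, 400))),
                     contigs)
  models <- vector("list", n_genes)
  ci <- 1L
  for (g in seq_len(n_genes)) {
    n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
    ex_w <- sample(seq(exon_len[1], exon_len[2]), n_ex, replace = TRUE)
    in_w <- if (n_ex > 1) {
      sample(seq(intron_len[1], intron_len[2]), n_ex - 1, replace = TRUE)
    } else integer(0)
    span <- sum(ex_w) + sum(in_w)
    ## find a contig with room, starting from the current one
    placed <- FALSE
    for (try in seq_along(contigs)) {
      ctg <- contigs[ci]
      if (cursor[ctg] + span + 200L < clen[ctg]) { placed <- TRUE; break }
      ci <- ci %% length(contigs) + 1L
    }
    if (!placed) {
      stop("cannot place gene ", g, " of ", n_genes,
           ": contigs too short for the requested layout")
    }
    ctg <- contigs[ci]
    start <- cursor[ctg]
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- start
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + ex_w[i] - 1L
      pos <- ends[i] + (if (i < n_ex) in_w[i] else 0L) + 1L
    }
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("gene%03d", g)
    cds <- if (with_cds) {
      c(starts[1] + utr, ends[n_ex] - utr)
    } else NULL
    tm <- transcript_model(paste0(gid, ".t1"), ctg, strand, starts, ends,
                           gene_id = gid, cds = cds)
    ## write canonical dinucleotides at every intron boundary
    intr <- transcript_introns(tm)
    if (nrow(intr) > 0) {
      don <- if (strand == "+") "GT" else "CT"
      acc <- if (strand == "+") "AG" else "AC"
      for (i in seq_len(nrow(intr))) {
        genome <- patch_genome(genome, ctg, intr$start[i], don)
        genome <- patch_genome(genome, ctg, intr$end[i] - 1L, acc)
      }
    }
    models[[g]] <- tm
    gap <- sample(seq(intergenic[1], intergenic[2]), 1)
    cursor[ctg] <- ends[n_ex] + gap
    ci <- ci %% length(contigs) + 1L
  }
  names(models) <- vapply(models, function(m) m$gene_id, character(1))
  list(genome = genome, models = models)
}

#' Verify canonical splice dinucleotides of gene models
#'
#' Scans the genome at every emitted intron boundary and reports the
#' fraction whose coding-strand dinucleotides are `GT..AG`.
#'
#' @param models list of [transcript_model()] objects.
#' @param genome genome the models live on.
#' @return fraction in `[0, 1]`; `NaN` when no introns exist.
#' @export
canonical_splice_fraction <- function(models, genome) {
  seqs <- genome_sequences(genome)
  ok <- 0L; tot <- 0L
  for (tm in models) {
    intr <- transcript_introns(tm)
    if (nrow(intr) == 0) next
    s <- seqs[[tm$contig]]
    for (i in seq_len(nrow(intr))) {
      left <- substr(s, intr$start[i], intr$start[i] + 1L)
      right <- substr(s, intr$end[i] - 1L, intr$end[i])
      hit <- if (tm$strand == "+") {
        left == "GT" && right == "AG"
      } else {
        left == "CT" && right == "AC"
      }
      ok <- ok + hit; tot <- tot + 1L
    }
  }
  ok / tot
}
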