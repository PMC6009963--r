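#' Intron-chain match between an assembled and a reference model
#'
#' `TRUE` iff the two models have identical ordered intron chains on the
#' same contig and strand; terminal-end differences are allowed. The
#' membership rule used when assigning short-read assemblies to long-read
#' transcripts.
#'
#' @param assembled,reference [transcript_model()] objects.
#' @return logical flag.
#' @export
intron_chain_match <- function(assembled, reference) {
  identical_intron_chain(assembled, reference)
}

#' Expression filter over a replicate-level FPKM table
#'
#' A transcript counts as expressed in a tissue when its assembly matched
#' the reference intron chain and its FPKM reaches `min_fpkm` (inclusive)
#' in at least `min_replicates` replicates of that tissue.
#'
#' @param records data.frame: `transcript_id`, `tissue`, `replicate`,
#'   `fpkm`, `intron_chain_matched` (logical; assumed `TRUE` when absent).
#' @param min_fpkm inclusive FPKM threshold (default 0.01).
#' @param min_replicates minimal number of passing replicates (default 2).
#' @return data.frame of expressed `(transcript_id, tissue)` pairs with the
#'   number of passing replicates.
#' @export
expression_filter <- function(records, min_fpkm = 0.01,
                              min_replicates = 2L) {
  stopifnot(all(records$fpkm >= 0))
  if (is.null(records$intron_chain_matched)) {
    records$intron_chain_matched <- TRUE
  }
  key <- paste(records$transcript_id, records$tissue, records$replicate)
  if (anyDuplicated(key)) stop("duplicate (transcript, tissue, replicate)")
  pass <- records$intron_chain_matched & records$fpkm >= min_fpkm
  agg <- stats::aggregate(pass,
                          by = list(transcript_id = records$transcript_id,
                                    tissue = records$tissue),
                          FUN = sum)
  names(agg)[3] <- "n_pass"
  out <- agg[agg$n_pass >= min_replicates, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-tissue expression summary
#'
#' Counts expressed transcripts per tissue, the set shared by all tissues
#' (intersection) and the tissue-specific sets (expressed in exactly one
#' tissue; the sets are pairwise disjoint by construction).
#'
#' @param expressed data.frame from [expression_filter()] (columns
#'   `transcript_id`, `tissue`).
#' @return list: `per_tissue` (data.frame `tissue`, `n_expressed`),
#'   `shared_by_all` (character vector), `tissue_specific` (named list of
#'   character vectors).
#' @export
tissue_summary <- function(expressed) {
  tissues <- unique(expressed$tissue)
  if (length(tissues) == 0) stop("no tissues in the expressed table")
  sets <- lapply(split(expressed$transcript_id, expressed$tissue), unique)
  per_tissue <- data.frame(tissue = names(sets),
                           n_expressed = vapply(sets, length, integer(1)))
  rownames(per_tissue) <- NULL
  n_tissues <- table(unique(expressed[c("transcript_id", "tissue")])$transcript_id)
  shared <- Reduce(intersect, sets)
  specific <- lapply(sets, function(s) {
    s[n_tissues[s] == 1]
  })
  list(per_tissue = per_tissue, shared_by_all = sort(shared),
       tissue_specific = specific)
}

#' Longest forward-frame open reading frame
#'
#' Scans the three forward frames of the given (sense) sequence for the
#' longest ATG-to-stop ORF and returns its length in nucleotides including
#' the stop codon. `0` when no complete ORF exists.
#'
#' @param sequence DNA string.
#' @return ORF length in nt.
#' @examples
#' longest_orf("ATGTAA")  # 6
#' @export
longest_orf <- function(sequence) {
  n <- nchar(sequence)
  if (n < 6) return(0L)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3
    if (n_cod < 2) next
    cod <- substring(sequence, f + 1 + 3 * (seq_len(n_cod) - 1),
                     f + 3 * seq_len(n_cod))
    atg <- which(cod == "ATG")
    stp <- which(cod %in% stops)
    if (length(atg) == 0 || length(stp) == 0) next
    ## for each ATG the first stop at or after it; open frames discarded
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    len <- (nxt - atg + 1L) * 3L
    len <- len[!is.na(len)]
    if (length(len)) best <- max(best, max(len))
  }
  as.integer(best)
}

#' Long non-coding RNA candidacy cascade
#'
#' Stage 1 keeps transcripts whose longest ORF is at most `max_orf` nt
#' (inclusive); stage 2 removes candidates with a protein (coding) hit;
#' stage 3 grades the survivors by coding-potential score: `strong` below
#' `strong_cut` (strict), `weak` in `[strong_cut, 0)`, otherwise `none`.
#' When transcript models and an annotation are supplied, each survivor is
#' placed in its genomic context: `sense` / `antisense` exonic overlap,
#' `intronic`, or `intergenic`.
#'
#' @param sequences named character vector of transcript sequences.
#' @param coding_hits character vector of transcript ids with a protein
#'   homology hit.
#' @param cp_scores named numeric coding-potential scores (negative =
#'   non-coding-like). Required for every candidate surviving stage 2.
#' @param max_orf inclusive ORF-length cutoff in nt (default 350).
#' @param strong_cut strict score cutoff for strong candidates (default -1).
#' @param models optional named list of [transcript_model()]s (same ids as
#'   `sequences`) for context assignment.
#' @param annotation optional reference annotation (list of models).
#' @return data.frame: `transcript_id`, `longest_orf_len`, `candidate`,
#'   `coding_hit`, `cp_score`, `call`, `context`.
#' @export
lnc_cascade <- function(sequences, coding_hits = character(0),
                        cp_scores = numeric(0), max_orf = 350L,
                        strong_cut = -1.0, models = NULL,
                        annotation = NULL) {
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by transcript id")
  orf <- vapply(sequences, longest_orf, integer(1))
  candidate <- orf <= max_orf
  hit <- ids %in% coding_hits
  surviving <- candidate & !hit
  score <- setNames(rep(NA_real_, length(ids)), ids)
  score[names(cp_scores)] <- cp_scores
  if (any(surviving & is.na(score))) {
    stop("missing coding-potential score for: ",
         paste(ids[surviving & is.na(score)], collapse = ", "))
  }
  call <- rep("none", length(ids))
  call[surviving & score < strong_cut] <- "strong"
  call[surviving & score >= strong_cut & score < 0] <- "weak"
  context <- rep(NA_character_, length(ids))
  if (!is.null(models) && !is.null(annotation)) {
    for (i in which(surviving)) {
      context[i] <- lnc_context(models[[ids[i]]], annotation)
    }
  }
  out <- data.frame(transcript_id = ids, longest_orf_len = orf,
                    candidate = candidate, coding_hit = hit,
                    cp_score = unname(score), call = call,
                    context = context)
  rownames(out) <- NULL
  out
}

## genomic context of a candidate: sense / antisense exonic overlap,
## intronic containment, else intergenic
lnc_context <- function(model, annotation) {
  if (is.null(model)) return(NA_character_)
  qs <- transcript_span(model)
  genes <- annotation_genes(annotation)
  ov <- Filter(function(g) g$contig == model$contig &&
                 overlaps(qs[1], qs[2], g$start, g$end), genes)
  if (length(ov) == 0) return("intergenic")
  exon_ov_strands <- character(0)
  for (g in ov) for (m in g$models) {
    if (any(outer(model$exon_start, m$exon_end, `<=`) &
              outer(model$exon_end, m$exon_start, `>=`))) {
      exon_ov_strands <- c(exon_ov_strands, m$strand)
    }
  }
  if (length(exon_ov_strands)) {
    return(if (model$strand %in% exon_ov_strands) "sense" else "antisense")
  }
  for (g in ov) for (m in g$models) {
    mi <- transcript_introns(m)
    if (nrow(mi) > 0 && any(contains(mi$start, mi$end, qs[1], qs[2]))) {
      return("intronic")
    }
  }
  if (ov[[1]]$strand == model$strand) "sense" else "antisense"
}

#' Homology-hit threshold filter with optional reciprocal-best requirement
#'
#' Keeps hits with e-value strictly below `max_evalue` and bit-score at
#' least `min_bscore_fraction` of the query's best bit-score. With
#' `bidirectional = TRUE` the query/subject pair must additionally be
#' mutual best hits (by raw bit-score) in the table. Typical settings:
#' `(1e-20, 0.93)` for conservative homology screens and `(1e-10, 0.90)`
#' for annotation transfer.
#'
#' @param hits data.frame: `query`, `subject`, `evalue`, `bitscore`.
#' @param max_evalue strict e-value cutoff.
#' @param min_bscore_fraction fraction of the per-query best bit-score a
#'   hit must reach (inclusive).
#' @param bidirectional require mutual best hits (default `FALSE`).
#' @return the kept rows of `hits`.
#' @export
homology_threshold_filter <- function(hits, max_evalue = 1e-10,
                                      min_bscore_fraction = 0.90,
                                      bidirectional = FALSE) {
  need <- c("query", "subject", "evalue", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("malformed hit table, missing: ",
                         paste(miss, collapse = ", "))
  bad <- which(is.na(hits$evalue) | is.na(hits$bitscore) |
                 hits$evalue < 0)
  if (length(bad)) stop("malformed hit table row ", bad[1])
  best_q <- tapply(hits$bitscore, hits$query, max)
  keep <- hits$evalue < max_evalue &
    hits$bitscore >= min_bscore_fraction * best_q[hits$query]
  if (bidirectional) {
    best_hit <- function(by) {
      o <- order(-hits$bitscore, hits$evalue)
      h <- hits[o, , drop = FALSE]
      setNames(h[[setdiff(c("query", "subject"), by)]][!duplicated(h[[by]])],
               h[[by]][!duplicated(h[[by]])])
    }
    fwd <- best_hit("query")     # query -> best subject
    rev <- best_hit("subject")   # subject -> best query
    mutual <- fwd[hits$query] == hits$subject &
      rev[hits$subject] == hits$query
    keep <- keep & !is.na(mutual) & mutual
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
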