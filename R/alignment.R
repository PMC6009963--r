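#' Transcript-to-genome alignment table
#'
#' Alignments are plain data.frames with one row per alignment segment and
#' (at least) the columns `read_id`, `contig`, `strand`, `start`, `end`,
#' `read_len`, `L` (aligned length in bp) and `K` (mismatch plus indel
#' count over the aligned bases; indel bases and mismatches are counted
#' uniformly). `transcript_alignments()` validates and normalises such a
#' table.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame, class `transcript_alignments`.
#' @export
transcript_alignments <- function(df) {
  need <- c("read_id", "contig", "strand", "start", "end", "read_len",
            "L", "K")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing alignment columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$L < 1)) stop("aligned length L must be >= 1")
  if (any(df$K < 0 | df$K > df$L)) stop("K must satisfy 0 <= K <= L")
  class(df) <- c("transcript_alignments", "data.frame")
  df
}

#' Alignment identity and coverage
#'
#' Adds `identity = (L - K) / L` and `coverage = min(1, L / read_len)` to an
#' alignment table.
#'
#' @param alns alignment table (see [transcript_alignments()]).
#' @return the table with `identity` and `coverage` columns.
#' @export
compute_identity_coverage <- function(alns) {
  if (any(alns$L < 1)) stop("aligned length L must be >= 1")
  alns$identity <- (alns$L - alns$K) / alns$L
  alns$coverage <- pmin(1, alns$L / alns$read_len)
  alns
}

#' High-quality alignment filter
#'
#' Keeps alignments with at least `min_identity` identity and at least
#' `min_coverage` read coverage (both inclusive). Idempotent.
#'
#' @param alns alignment table; `identity`/`coverage` are computed when
#'   absent.
#' @param min_identity,min_coverage inclusive thresholds in `[0, 1]`
#'   (defaults 0.90 and 0.85).
#' @return the kept rows.
#' @export
filter_high_quality <- function(alns, min_identity = 0.90,
                                min_coverage = 0.85) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  if (is.null(alns$identity) || is.null(alns$coverage)) {
    alns <- compute_identity_coverage(alns)
  }
  alns[alns$identity >= min_identity & alns$coverage >= min_coverage, ,
       drop = FALSE]
}

#' Keep only the best alignment per read
#'
#' The best alignment maximises `identity * coverage`; exact ties are
#' broken deterministically by smallest `(contig, start)`.
#'
#' @param alns alignment table with one row per candidate alignment.
#' @return one row per `read_id`.
#' @export
select_best_alignment <- function(alns) {
  if (nrow(alns) == 0) stop("no alignments supplied")
  if (is.null(alns$identity) || is.null(alns$coverage)) {
    alns <- compute_identity_coverage(alns)
  }
  score <- alns$identity * alns$coverage
  o <- order(alns$read_id, -score, alns$contig, alns$start)
  alns <- alns[o, , drop = FALSE]
  out <- alns[!duplicated(alns$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mis-mapping p-value of an alignment's mismatch count
#'
#' Under the model that sequencing errors strike each aligned base
#' independently with a fixed library-specific probability `p`, the number
#' of errors in an `L` bp alignment is Binomial(L, p). The upper-tail
#' probability that at least `K` errors occur is evaluated with the normal
#' (de Moivre-Laplace) approximation
#' \deqn{1 - \Phi\left((K - Lp) / \sqrt{Lp(1-p)}\right).}
#' A small value means the observed mismatch count is implausibly high for
#' a correctly mapped read, i.e. evidence of alignment to a homologous
#' (wrong) locus. Monotone non-increasing in `K`.
#'
#' @param K observed mismatch + indel count (vectorised).
#' @param L aligned length in bp (>= 1).
#' @param p per-base error rate, strictly between 0 and 1.
#' @param continuity apply the 0.5 continuity correction (off by default).
#' @return upper-tail probabilities in `[0, 1]`.
#' @examples
#' mismap_pvalue(20, 1000, 0.01)
#' @export
mismap_pvalue <- function(K, L, p, continuity = FALSE) {
  stopifnot(all(L >= 1), all(K >= 0), all(K <= L))
  if (any(p <= 0) || any(p >= 1)) {
    stop("p must be strictly between 0 and 1 (degenerate variance otherwise)")
  }
  cc <- if (continuity) 0.5 else 0
  z <- (K - cc - L * p) / sqrt(L * p * (1 - p))
  1 - pnorm(z)
}

#' Mis-mapping decision rule
#'
#' Flags an alignment as a putative mis-mapping when its mismatch count
#' exceeds `L * (p + margin)` (strictly), the fixed-margin form of the
#' tail test: at the default margin of 0.03 the corresponding upper-tail
#' probability is vanishingly small for realistic alignment lengths, so
#' flagged reads are confidently mis-aligned.
#'
#' @inheritParams mismap_pvalue
#' @param margin additive error-rate margin (default 0.03).
#' @return data.frame: `K`, `L`, `p`, `threshold_K`, `pvalue`, `flagged`.
#' @examples
#' mismap_flag(c(40, 41), 1000, 0.01)   # threshold_K = 40: only 41 flags
#' @export
mismap_flag <- function(K, L, p, margin = 0.03) {
  stopifnot(margin >= 0)
  n <- max(length(K), length(L), length(p))
  K <- rep_len(K, n); L <- rep_len(L, n); p <- rep_len(p, n)
  threshold_K <- L * (p + margin)
  data.frame(K = K, L = L, p = p, threshold_K = threshold_K,
             pvalue = mismap_pvalue(K, L, p),
             flagged = K > threshold_K)
}

#' Error rates of the mis-mapping test on truth-labelled alignments
#'
#' Positives are alignments accepted as correct (not flagged). With that
#' orientation the false positive rate is the fraction of wrong-locus
#' alignments that escape the flag, and the false negative rate is the
#' fraction of correct alignments that are flagged. Both orientations are
#' returned so either reading of "positive" is available.
#'
#' @param flagged logical vector from [mismap_flag()].
#' @param correct logical truth label per alignment (`TRUE` = aligned to
#'   its true locus).
#' @return list: `fpr` (wrong-locus accepted), `fnr` (correct flagged),
#'   `wrong_flagged`, `correct_accepted`, and the underlying counts.
#' @export
evaluate_fpr_fnr <- function(flagged, correct) {
  if (length(flagged) != length(correct)) {
    stop("flagged and correct must have equal length")
  }
  if (anyNA(flagged) || anyNA(correct)) stop("missing truth labels")
  n_wrong <- sum(!correct); n_corr <- sum(correct)
  list(
    fpr = if (n_wrong) sum(!flagged & !correct) / n_wrong else NA_real_,
    fnr = if (n_corr) sum(flagged & correct) / n_corr else NA_real_,
    wrong_flagged = if (n_wrong) sum(flagged & !correct) / n_wrong
                    else NA_real_,
    correct_accepted = if (n_corr) sum(!flagged & correct) / n_corr
                       else NA_real_,
    n_correct = n_corr, n_wrong = n_wrong
  )
}

#' Derive alignments for simulated reads from their planted truth
#'
#' Convenience for synthetic data: reconstructs, for each read, the
#' decorated reference sequence it was generated from and counts the edit
#' distance between the two, giving the aligned length `L` and error count
#' `K` without running a spliced aligner (whose role is out of scope).
#' Chimeric reads yield one segment row per source locus with the edit
#' count apportioned by segment length.
#'
#' @param sim result of [simulate_long_reads()].
#' @param isoforms,genome the isoform set and genome the reads came from.
#' @param primer5,primer3,polya_len decoration parameters used in the
#'   simulation.
#' @return a [transcript_alignments()] table with `identity`/`coverage`.
#' @export
alignments_from_truth <- function(sim, isoforms, genome,
                                  primer5 = default_primers()$p5,
                                  primer3 = default_primers()$p3,
                                  polya_len = 30L) {
  iso_ids <- vapply(isoforms, function(m) m$id, character(1))
  names(isoforms) <- iso_ids
  iso_seq <- vapply(isoforms, transcript_sequence, character(1),
                    genome = genome)
  truth <- sim$truth
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    read <- sim$reads[[tr$read_id]]
    if (tr$rc) read <- revcomp(read)
    build <- function(core) {
      paste0(if (tr$has_5p) primer5 else "", core,
             if (tr$has_polya) strrep("A", polya_len) else "",
             if (tr$has_3p) primer3 else "")
    }
    if (tr$kind == "normal") {
      s <- iso_seq[[tr$source_isoform]]
      core <- substr(s, tr$trunc5 + 1L, nchar(s) - tr$trunc3)
      expected <- build(core)
      K <- as.integer(adist(read, expected))
      src <- isoforms[[tr$source_isoform]]
      sp <- transcript_span(src)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = tr$read_id, contig = src$contig, strand = src$strand,
        start = sp[1], end = sp[2], read_len = nchar(read),
        L = nchar(expected), K = K, segment = 1L
      )
    } else if (tr$kind == "fusion") {
      a <- isoforms[[tr$source_isoform]]
      b <- isoforms[[tr$source_isoform2]]
      expected <- build(paste0(iso_seq[[a$id]], iso_seq[[b$id]]))
      K <- as.integer(adist(read, expected))
      la <- nchar(iso_seq[[a$id]]); lb <- nchar(iso_seq[[b$id]])
      ka <- as.integer(round(K * la / (la + lb)))
      spa <- transcript_span(a); spb <- transcript_span(b)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = tr$read_id,
        contig = c(a$contig, b$contig),
        strand = c(a$strand, b$strand),
        start = c(spa[1], spb[1]), end = c(spa[2], spb[2]),
        read_len = nchar(read),
        L = c(la, lb), K = c(ka, K - ka), segment = c(1L, 2L)
      )
    }
    ## concatemers are triage rejects; no alignment rows for them
  }
  compute_identity_coverage(transcript_alignments(do.call(rbind, rows)))
}
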