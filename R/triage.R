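#' Strict length filter for raw reads
#'
#' Keeps reads strictly longer than `min_len` (the conventional "> 300 bp"
#' raw-read cutoff); the partition into kept and removed is exact.
#'
#' @param reads named character vector of read sequences.
#' @param min_len minimum length in bp (strict; default 300).
#' @return list with `kept` and `removed` named character vectors.
#' @export
filter_short_reads <- function(reads, min_len = 300L) {
  stopifnot(min_len >= 0)
  keep <- nchar(reads) > min_len
  list(kept = reads[keep], removed = reads[!keep])
}

## approximate occurrence of a primer in a sequence window;
## returns first match start (local coordinates) or NA, with the edit
## distance of the matched region as attribute "edits"
find_primer <- function(seq, primer, max_mismatch) {
  if (nchar(seq) < 1) return(NA_integer_)
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatch,
                                with.indels = TRUE)
  if (length(m) == 0) return(NA_integer_)
  ## pick the lowest-edit occurrence (matters for shadow matches of the
  ## complementary primer in single-primer library designs)
  ed <- adist(as.character(m), primer)[, 1]
  best <- which.min(ed)
  structure(BiocGenerics::start(m)[best], edits = ed[best])
}

## is there a polyA run of >= min_run with <= 10% non-A bases inside `region`?
has_polya_run <- function(region, min_run = 20L, max_nonA_frac = 0.1) {
  n <- nchar(region)
  if (n < min_run) return(FALSE)
  isA <- as.integer(strsplit(region, "", fixed = TRUE)[[1]] == "A")
  cs <- c(0L, cumsum(isA))
  need <- ceiling(min_run * (1 - max_nonA_frac))
  w <- min_run
  any(cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)] >= need)
}

## classify one oriented sequence; returns flags and primer positions
classify_one_strand <- function(seq, primer5, primer3, window, mm5, mm3,
                                min_polya) {
  n <- nchar(seq)
  head_end <- min(n, window + nchar(primer5))
  pos5 <- find_primer(substr(seq, 1, head_end), primer5, mm5)
  tail_start <- max(1L, n - window - nchar(primer3) + 1L)
  pos3_local <- find_primer(substr(seq, tail_start, n), primer3, mm3)
  pos3 <- if (is.na(pos3_local)) NA_integer_ else tail_start + pos3_local - 1L
  ## polyA immediately 5' of the 3' primer (or in the tail window if the
  ## primer itself was lost)
  region_end <- if (!is.na(pos3)) pos3 - 1L else n
  region_start <- max(1L, region_end - 3L * min_polya + 1L)
  polya <- if (region_end >= region_start) {
    has_polya_run(substr(seq, region_start, region_end), min_run = min_polya)
  } else FALSE
  edits <- sum(attr(pos5, "edits") %||% 0, attr(pos3, "edits") %||% 0)
  matched_len <- sum(if (!is.na(pos5)) nchar(primer5) else 0,
                     if (!is.na(pos3)) nchar(primer3) else 0)
  list(p5 = !is.na(pos5), p3 = !is.na(pos3), polya = polya,
       pos5 = as.integer(pos5), pos3 = as.integer(pos3),
       n_signals = sum(!is.na(pos5), !is.na(pos3), polya),
       edits = edits, matched_len = matched_len)
}

#' Classify the terminal signals of one long read
#'
#' Looks for the 5' primer within a terminal window at the read start, the
#' 3' primer within a terminal window at the read end (both allowing up to
#' `max_mismatch` edits, default 20% of the primer length) and a polyA run
#' of at least `min_polya` bases (tolerating one non-A per ten) immediately
#' upstream of the 3' primer. Both orientations are tried; the strand
#' showing more signals (an FL-consistent layout) wins, with ties going to
#' the forward strand. The read is FL iff all three signals are present;
#' otherwise one of the seven missing-signal classes is returned.
#'
#' @param seq read sequence (character scalar).
#' @param primer5,primer3 primer sequences, default [default_primers()].
#' @param min_polya minimal polyA run length (default 20).
#' @param max_mismatch maximal edits allowed in a primer match; default
#'   `ceiling(0.2 * nchar(primer))`, tolerant of raw long-read error rates.
#' @param window terminal search window in bp (default 100).
#' @return list: `class` (one of [signal_classes()]), presence flags `p5`,
#'   `p3`, `polya`, the matched `orientation` (`"+"` forward, `"-"` reverse
#'   complement) and primer positions on that orientation.
#' @export
classify_signals <- function(seq, primer5 = default_primers()$p5,
                             primer3 = default_primers()$p3,
                             min_polya = 20L, max_mismatch = NULL,
                             window = 100L) {
  stopifnot(nchar(primer5) > 0, nchar(primer3) > 0)
  mm5 <- max_mismatch %||% ceiling(0.2 * nchar(primer5))
  mm3 <- max_mismatch %||% ceiling(0.2 * nchar(primer3))
  fwd <- classify_one_strand(seq, primer5, primer3, window, mm5, mm3,
                             min_polya)
  rev <- classify_one_strand(revcomp(seq), primer5, primer3, window,
                             mm5, mm3, min_polya)
  ## the FL-consistent layout (more signals) wins; at equal signal counts
  ## an alignment-like primer score (matched length minus 4 per edit)
  ## decides, which resolves shadow matches of a complementary primer in
  ## single-primer library designs; final ties go to the forward strand
  score <- function(h) h$matched_len - 4 * h$edits
  rev_wins <- rev$n_signals > fwd$n_signals ||
    (rev$n_signals == fwd$n_signals && rev$n_signals > 0 &&
       score(rev) > score(fwd))
  hit <- if (rev_wins) c(rev, orientation = "-") else
    c(fwd, orientation = "+")
  hit$class <- signal_class_label(hit$p5, hit$p3, hit$polya)
  hit[c("class", "p5", "p3", "polya", "orientation", "pos5", "pos3")]
}

#' Flag putative artificial concatemers
#'
#' A read is flagged when either primer occurs in the read interior, i.e.
#' entirely outside both terminal windows, in either orientation - the
#' signature of two cDNAs joined in one molecule.
#'
#' @inheritParams classify_signals
#' @return logical flag.
#' @export
flag_concatemer <- function(seq, primer5 = default_primers()$p5,
                            primer3 = default_primers()$p3,
                            max_mismatch = NULL, window = 100L) {
  mm5 <- max_mismatch %||% ceiling(0.2 * nchar(primer5))
  mm3 <- max_mismatch %||% ceiling(0.2 * nchar(primer3))
  n <- nchar(seq)
  lo <- window + 1L
  interior_hit <- function(s, primer, mm) {
    hi <- n - window - nchar(primer) + 1L
    if (hi < lo) return(FALSE)
    mid <- substr(s, lo, n - window)
    !is.na(find_primer(mid, primer, mm))
  }
  interior_hit(seq, primer5, mm5) || interior_hit(seq, primer3, mm3) ||
    interior_hit(revcomp(seq), primer5, mm5) ||
    interior_hit(revcomp(seq), primer3, mm3)
}

#' Triage a set of raw long reads
#'
#' Applies the strict length filter, the 8-way signal classification and
#' the concatemer flag to every read and returns the per-read table.
#'
#' @param reads named character vector of read sequences.
#' @inheritParams classify_signals
#' @param min_len strict minimum read length (default 300).
#' @return data.frame: `read_id`, `length`, `length_pass`, `class`,
#'   `is_fl`, `p5`, `p3`, `polya`, `orientation`, `concatemer`.
#' @export
triage_reads <- function(reads, primer5 = default_primers()$p5,
                         primer3 = default_primers()$p3,
                         min_len = 300L, min_polya = 20L,
                         max_mismatch = NULL, window = 100L) {
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    cl <- classify_signals(reads[[i]], primer5, primer3, min_polya,
                           max_mismatch, window)
    data.frame(
      read_id = ids[i], length = nchar(reads[[i]]),
      length_pass = nchar(reads[[i]]) > min_len,
      class = cl$class, is_fl = cl$class == "FL",
      p5 = cl$p5, p3 = cl$p3, polya = cl$polya,
      orientation = cl$orientation,
      concatemer = flag_concatemer(reads[[i]], primer5, primer3,
                                   max_mismatch, window)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
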