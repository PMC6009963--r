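#' Default library primers
#'
#' The 5' primer is the template-switching oligo family used in full-length
#' cDNA library construction (PCR core plus the `TACGGG` template-switch
#' tail); the 3' primer is the reverse complement of the PCR core, which is
#' what appears at the 3' end of a sense-strand cDNA read after the polyA
#' tail. Any user-supplied pair is accepted wherever primers are taken.
#'
#' @return list with elements `p5` and `p3` (character DNA).
#' @export
default_primers <- function() {
  core <- "TAGTCGAACTGAGATCTCCAGCAG"
  list(p5 = paste0(core, "TACGGG"), p3 = revcomp(core))
}

## canonical 8-way signal class label from the three presence flags
signal_class_label <- function(p5, p3, polya) {
  if (p5 && p3 && polya) return("FL")
  miss <- c(if (!p5) "5p", if (!p3) "3p", if (!polya) "polyA")
  if (length(miss) == 3) "missing_all" else
    paste0("missing_", paste(miss, collapse = "_"))
}

#' The eight read signal classes
#'
#' All combinations of presence/absence of the 5' primer, 3' primer and
#' polyA tail; `FL` is the all-present class.
#'
#' @return character vector of the 8 class labels.
#' @export
signal_classes <- function() {
  combos <- expand.grid(p5 = c(TRUE, FALSE), p3 = c(TRUE, FALSE),
                        polya = c(TRUE, FALSE))
  unique(mapply(signal_class_label, combos$p5, combos$p3, combos$polya))
}

## default non-FL class mix: the three dominant observed classes
## (missing everything; missing 3' + polyA; missing 5') in ratio 47:21:22,
## remaining 10 shared by the four minor classes
default_nonfl_weights <- function() {
  c(missing_all = 47, missing_3p_polyA = 21, missing_5p = 22,
    missing_5p_polyA = 2.5, missing_5p_3p = 2.5,
    missing_polyA = 2.5, missing_3p = 2.5)
}

class_flags <- function(class) {
  miss <- switch(class,
    FL = character(0),
    missing_all = c("5p", "3p", "polyA"),
    missing_5p = "5p", missing_3p = "3p", missing_polyA = "polyA",
    missing_5p_3p = c("5p", "3p"), missing_5p_polyA = c("5p", "polyA"),
    missing_3p_polyA = c("3p", "polyA"),
    stop("unknown class ", class))
  c(p5 = !"5p" %in% miss, p3 = !"3p" %in% miss, polya = !"polyA" %in% miss)
}

#' Apply i.i.d. per-base sequencing errors
#'
#' Each base independently suffers an error with probability `p`; errors are
#' substitutions, single-base insertions or deletions with an
#' indel:substitution mix of `indel_frac : (1 - indel_frac)` (default 2:1,
#' typical of raw single-molecule long reads).
#'
#' @param seq DNA string.
#' @param p per-base error rate in `[0, 0.5]`.
#' @param indel_frac fraction of errors that are indels (split evenly
#'   between insertions and deletions).
#' @return list with `seq` (mutated string) and `n_errors` (count applied).
#' @export
apply_sequencing_errors <- function(seq, p, indel_frac = 2 / 3) {
  stopifnot(p >= 0, p <= 0.5)
  if (p == 0 || nchar(seq) == 0) return(list(seq = seq, n_errors = 0L))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  err <- runif(length(b)) < p
  n <- sum(err)
  if (n == 0) return(list(seq = seq, n_errors = 0L))
  type <- sample(c("sub", "ins", "del"), n, replace = TRUE,
                 prob = c(1 - indel_frac, indel_frac / 2, indel_frac / 2))
  idx <- which(err)
  out <- b
  is_sub <- idx[type == "sub"]
  if (length(is_sub)) {
    repl <- sample(DNA_BASES, length(is_sub), replace = TRUE)
    same <- repl == b[is_sub]
    ## force substitutions to change the base: rotate A->C->G->T->A
    repl[same] <- DNA_BASES[match(repl[same], DNA_BASES) %% 4L + 1L]
    out[is_sub] <- repl
  }
  is_ins <- idx[type == "ins"]
  if (length(is_ins)) {
    out[is_ins] <- paste0(b[is_ins],
                          sample(DNA_BASES, length(is_ins), replace = TRUE))
  }
  out[idx[type == "del"]] <- ""
  list(seq = paste(out, collapse = ""), n_errors = as.integer(n))
}

#' Simulate long reads from isoforms with planted truth
#'
#' Emulates raw full-length cDNA sequencing: each read derives from one
#' isoform, is decorated according to its drawn signal class (FL reads carry
#' the 5' primer, a polyA tail of `polya_len` and the 3' primer; non-FL
#' reads omit signals per `class_weights` and are truncated at the ends that
#' lost their signals), suffers i.i.d. per-base errors at rate `p`, and is
#' emitted on a random strand. Chimeric reads can be planted: `fusion_spec`
#' rows concatenate the transcripts of two isoforms (expected to lie at
#' distinct loci) into one FL-decorated read; `concatemer_spec` rows join
#' two fully decorated cDNAs into one read, the library artifact detected by
#' [flag_concatemer()].
#'
#' @param isoforms named list of [transcript_model()] objects.
#' @param genome genome the isoforms live on.
#' @param reads_per_isoform scalar or per-isoform vector of read counts.
#' @param p per-base error rate in `[0, 0.2]`.
#' @param fl_fraction fraction of reads drawn from the FL class.
#' @param class_weights named non-FL class weights, default
#'   [default_nonfl_weights()].
#' @param fusion_spec optional data.frame with columns `isoform_a`,
#'   `isoform_b`; one chimeric read per row.
#' @param concatemer_spec optional data.frame like `fusion_spec`; one
#'   artificial concatemer per row.
#' @param primer5,primer3 primer sequences, default [default_primers()].
#' @param polya_len polyA tail length (>= 20 so FL reads satisfy the polyA
#'   detection rule).
#' @param rc_fraction fraction of reads emitted reverse-complemented.
#' @param max_truncation maximal fraction of the transcript removed at a
#'   truncated end.
#' @param seed optional integer seed.
#' @return list with `reads` (named character vector), `truth` (one row per
#'   read: source isoform, kind, signal class and flags, truncations,
#'   realised error count, orientation) and `fusion_truth` (per planted
#'   chimera: the two genomic segments and their read fractions; `NULL` when
#'   none planted).
#' @export
simulate_long_reads <- function(isoforms, genome, reads_per_isoform = 1L,
                                p = 0.02, fl_fraction = 0.5,
                                class_weights = default_nonfl_weights(),
                                fusion_spec = NULL, concatemer_spec = NULL,
                                primer5 = default_primers()$p5,
                                primer3 = default_primers()$p3,
                                polya_len = 30L, rc_fraction = 0.5,
                                max_truncation = 0.3, seed = NULL) {
  if (length(isoforms) == 0) stop("empty isoform set")
  stopifnot(p >= 0, p <= 0.2, fl_fraction >= 0, fl_fraction <= 1,
            polya_len >= 20)
  maybe_seed(seed)
  iso_ids <- vapply(isoforms, function(m) m$id, character(1))
  names(isoforms) <- iso_ids
  iso_seq <- vapply(isoforms, transcript_sequence, character(1),
                    genome = genome)
  n_per <- rep_len(as.integer(reads_per_isoform), length(isoforms))
  src <- rep(iso_ids, n_per)
  n_normal <- length(src)
  nonfl <- class_weights / sum(class_weights)

  reads <- character(0); truth <- list(); fus <- list()
  rid <- 0L
  emit <- function(core, class, kind, source, source2 = NA_character_,
                   trunc5 = 0L, trunc3 = 0L) {
    rid <<- rid + 1L
    id <- sprintf("read%06d", rid)
    fl <- class_flags(class)
    parts <- c(if (fl["p5"]) primer5 else "",
               core,
               if (fl["polya"]) strrep("A", polya_len) else "",
               if (fl["p3"]) primer3 else "")
    r <- paste(parts, collapse = "")
    e <- apply_sequencing_errors(r, p)
    rc <- runif(1) < rc_fraction
    reads[id] <<- if (rc) revcomp(e$seq) else e$seq
    truth[[id]] <<- data.frame(
      read_id = id, source_isoform = source, source_isoform2 = source2,
      kind = kind, class = class,
      has_5p = unname(fl["p5"]), has_3p = unname(fl["p3"]),
      has_polya = unname(fl["polya"]), is_fl = class == "FL",
      error_rate = p, rc = rc, trunc5 = trunc5, trunc3 = trunc3,
      n_errors = e$n_errors, read_len = nchar(reads[id])
    )
    id
  }

  for (i in seq_len(n_normal)) {
    s <- iso_seq[[src[i]]]
    class <- if (runif(1) < fl_fraction) "FL" else
      sample(names(nonfl), 1, prob = nonfl)
    fl <- class_flags(class)
    t5 <- 0L; t3 <- 0L
    len <- nchar(s)
    if (!fl["p5"]) t5 <- as.integer(runif(1, 0, max_truncation * len))
    if (!fl["p3"] && !fl["polya"]) {
      t3 <- as.integer(runif(1, 0, max_truncation * len))
    }
    if (t5 + t3 >= len) { t5 <- 0L; t3 <- 0L }
    core <- substr(s, t5 + 1L, len - t3)
    emit(core, class, "normal", src[i], trunc5 = t5, trunc3 = t3)
  }

  if (!is.null(fusion_spec) && nrow(fusion_spec) > 0) {
    for (i in seq_len(nrow(fusion_spec))) {
      a <- isoforms[[fusion_spec$isoform_a[i]]]
      b <- isoforms[[fusion_spec$isoform_b[i]]]
      if (is.null(a) || is.null(b)) stop("fusion_spec names unknown isoform")
      sa <- iso_seq[[a$id]]; sb <- iso_seq[[b$id]]
      id <- emit(paste0(sa, sb), "FL", "fusion", a$id, b$id)
      spa <- transcript_span(a); spb <- transcript_span(b)
      tot <- nchar(sa) + nchar(sb)
      fus[[id]] <- data.frame(
        read_id = id,
        contig_a = a$contig, start_a = spa[1], end_a = spa[2],
        strand_a = a$strand, len_a = nchar(sa), frac_a = nchar(sa) / tot,
        contig_b = b$contig, start_b = spb[1], end_b = spb[2],
        strand_b = b$strand, len_b = nchar(sb), frac_b = nchar(sb) / tot
      )
    }
  }

  if (!is.null(concatemer_spec) && nrow(concatemer_spec) > 0) {
    for (i in seq_len(nrow(concatemer_spec))) {
      a <- isoforms[[concatemer_spec$isoform_a[i]]]
      b <- isoforms[[concatemer_spec$isoform_b[i]]]
      if (is.null(a) || is.null(b)) {
        stop("concatemer_spec names unknown isoform")
      }
      ## two complete decorated cDNAs joined in one read: the FL emit()
      ## decoration supplies the outer primers, the inner pair sits in the
      ## read interior
      core <- paste0(iso_seq[[a$id]], strrep("A", polya_len), primer3,
                     primer5, iso_seq[[b$id]])
      emit(core, "FL", "concatemer", a$id, b$id)
    }
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth,
       fusion_truth = if (length(fus)) do.call(rbind, fus) else NULL)
}

#' Simulate short-read junction support
#'
#' Per-junction read counts are the sum of the sequencing depths of the
#' isoforms containing that junction, i.e. support proportional to
#' expression; counts are emitted per sample. Deterministic by design so
#' planted support levels are exact.
#'
#' @param isoforms named list of [transcript_model()] objects.
#' @param depth scalar or per-isoform vector of read depth.
#' @param n_samples number of identically covered samples to emit.
#' @return data.frame: `sample`, `contig`, `start`, `end`, `strand`,
#'   `count` (one row per junction per sample).
#' @export
simulate_short_read_support <- function(isoforms, depth, n_samples = 1L) {
  stopifnot(all(depth >= 0), n_samples >= 1)
  depth <- rep_len(depth, length(isoforms))
  tally <- list()
  for (i in seq_along(isoforms)) {
    j <- transcript_junctions(isoforms[[i]])
    if (nrow(j) == 0) next
    j$count <- depth[i]
    tally[[length(tally) + 1L]] <- j
  }
  if (length(tally) == 0) {
    return(data.frame(sample = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), count = numeric(0)))
  }
  tab <- do.call(rbind, tally)
  agg <- stats::aggregate(count ~ contig + start + end + strand, tab, sum)
  out <- do.call(rbind, lapply(seq_len(n_samples), function(s) {
    cbind(sample = sprintf("S%02d", s), agg)
  }))
  rownames(out) <- NULL
  out
}

#' Build a paired-read locus-link table for planted chimeric reads
#'
#' Emits one unordered locus pair per planted chimera, with a configurable
#' number of supporting read pairs for a chosen subset (the "genuinely
#' co-transcribed" loci) and a sub-threshold count for the rest.
#'
#' @param fusion_truth the `fusion_truth` table of [simulate_long_reads()].
#' @param supported_ids read ids whose locus pair receives full support.
#' @param n_supported read-pair count for supported pairs (>= 5 validates).
#' @param n_unsupported read-pair count for the remaining pairs.
#' @return data.frame: `contig_a`, `pos_a`, `contig_b`, `pos_b`, `n_pairs`.
#' @export
make_locus_links <- function(fusion_truth, supported_ids,
                             n_supported = 8L, n_unsupported = 2L) {
  if (is.null(fusion_truth) || nrow(fusion_truth) == 0) {
    return(data.frame(contig_a = character(0), pos_a = integer(0),
                      contig_b = character(0), pos_b = integer(0),
                      n_pairs = integer(0)))
  }
  data.frame(
    contig_a = fusion_truth$contig_a,
    pos_a = as.integer((fusion_truth$start_a + fusion_truth$end_a) / 2),
    contig_b = fusion_truth$contig_b,
    pos_b = as.integer((fusion_truth$start_b + fusion_truth$end_b) / 2),
    n_pairs = ifelse(fusion_truth$read_id %in% supported_ids,
                     as.integer(n_supported), as.integer(n_unsupported))
  )
}
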