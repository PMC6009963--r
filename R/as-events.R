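#' Enumerate alternative-splicing events among a gene's isoforms
#'
#' All ordered isoform pairs are compared structurally and the resulting
#' events are deduplicated by `(type, variable-region coordinates)`:
#'
#' * `IR` (intron retention) - an exon of one isoform fully spans an
#'   intron of the other; coordinates are the retained intron.
#' * `ES` (exon skipping) - an internal exon of one isoform lies entirely
#'   within an intron of the other; coordinates are the skipped exon.
#' * `A5SS` / `A3SS` - two introns share one boundary and differ at the
#'   other; the alternative boundary is the donor (5') or acceptor (3')
#'   side *in transcription direction*, so the genome-left intron boundary
#'   is the donor on `+` and the acceptor on `-`. Coordinates are the
#'   variable region between the two alternative boundaries. Pairs whose
#'   differing region swallows a complete exon of either isoform are left
#'   to the ES/IR rules.
#' * `OTHER` - an isoform starts or ends inside an intron of the other
#'   (including alternative terminal exons), reported only when the two
#'   isoforms also share at least one junction; coordinates are the host
#'   intron.
#'
#' @param isoforms list of [transcript_model()] objects of one gene; all
#'   must share a strand.
#' @param gene_id gene label on the events (defaults to the first
#'   isoform's).
#' @return data.frame: `gene_id`, `type`, `contig`, `start`, `end`,
#'   `strand`, `isoforms` (comma-joined participating isoform ids).
#' @export
infer_as_events <- function(isoforms, gene_id = NULL) {
  stopifnot(length(isoforms) >= 1)
  strands <- unique(vapply(isoforms, function(m) m$strand, character(1)))
  if (length(strands) > 1) stop("isoforms on mixed strands")
  gene_id <- gene_id %||% isoforms[[1]]$gene_id
  strand <- strands[1]
  contig <- isoforms[[1]]$contig
  events <- list()
  add <- function(type, s, e, who) {
    key <- paste(type, s, e)
    if (is.null(events[[key]])) {
      events[[key]] <<- list(type = type, start = s, end = e, iso = who)
    } else {
      events[[key]]$iso <<- union(events[[key]]$iso, who)
    }
  }
  n <- length(isoforms)
  if (n >= 2) for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    x <- isoforms[[a]]; y <- isoforms[[b]]
    xi <- transcript_introns(x); yi <- transcript_introns(y)
    who <- c(x$id, y$id)
    nx <- length(x$exon_start)
    ## IR: an exon of x fully spans an intron of y
    if (nrow(yi) > 0) for (e in seq_len(nx)) {
      sp <- which(x$exon_start[e] < yi$start & x$exon_end[e] > yi$end)
      for (j in sp) add("IR", yi$start[j], yi$end[j], who)
    }
    ## ES: an internal exon of x entirely inside an intron of y
    if (nx >= 3 && nrow(yi) > 0) for (e in 2:(nx - 1)) {
      inside <- any(yi$start < x$exon_start[e] & yi$end > x$exon_end[e])
      if (inside) add("ES", x$exon_start[e], x$exon_end[e], who)
    }
    ## A5SS / A3SS: introns sharing exactly one boundary
    if (nrow(xi) > 0 && nrow(yi) > 0) {
      for (i in seq_len(nrow(xi))) for (j in seq_len(nrow(yi))) {
        share_l <- xi$start[i] == yi$start[j]
        share_r <- xi$end[i] == yi$end[j]
        if (share_l == share_r) next   # identical or unrelated introns
        lo <- c(xi$start[i], yi$start[j]); hi <- c(xi$end[i], yi$end[j])
        big_s <- min(lo); big_e <- max(hi)
        ## differing region covered by a full exon of either isoform ->
        ## exon-skipping/retention territory, not an alternative site
        exon_inside <- any(
          c(x$exon_start > big_s & x$exon_end < big_e,
            y$exon_start > big_s & y$exon_end < big_e))
        if (exon_inside) next
        if (share_l) {
          type <- if (strand == "+") "A3SS" else "A5SS"
          add(type, min(hi) + 1L, max(hi), who)
        } else {
          type <- if (strand == "+") "A5SS" else "A3SS"
          add(type, min(lo), max(lo) - 1L, who)
        }
      }
    }
    ## OTHER: x starts or ends inside an intron of y (shared junction
    ## required so plain overlapping genes do not fire)
    if (nrow(yi) > 0 && n_shared_junctions(x, y) > 0) {
      xs <- transcript_span(x)
      for (bnd in xs) {
        j <- which(yi$start < bnd & yi$end > bnd)
        for (k in j) add("OTHER", yi$start[k], yi$end[k], who)
      }
    }
  }
  if (length(events) == 0) {
    return(data.frame(gene_id = character(0), type = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      isoforms = character(0)))
  }
  out <- do.call(rbind, lapply(events, function(ev) {
    data.frame(gene_id = gene_id, type = ev$type, contig = contig,
               start = ev$start, end = ev$end, strand = strand,
               isoforms = paste(sort(ev$iso), collapse = ","))
  }))
  out <- out[order(out$type, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Label isoforms that contain at least one AS event
#'
#' @param isoforms list of [transcript_model()] objects.
#' @param events event table from [infer_as_events()].
#' @return named logical vector, `TRUE` for every isoform participating in
#'   at least one event.
#' @export
label_as_transcripts <- function(isoforms, events) {
  ids <- vapply(isoforms, function(m) m$id, character(1))
  involved <- unique(unlist(strsplit(events$isoforms, ",", fixed = TRUE)))
  setNames(ids %in% involved, ids)
}

#' Short-read support of splice junctions
#'
#' Junctions are matched to the support table by exact
#' `(contig, start, end, strand)` key. A junction is supported when it
#' reaches `min_reads` in at least one sample; the mean-over-samples
#' variant is also reported.
#'
#' @param junctions data.frame of junctions (`contig`, `start`, `end`,
#'   `strand`), e.g. from [transcript_junctions()].
#' @param support support table (`sample`, `contig`, `start`, `end`,
#'   `strand`, `count`), e.g. from [simulate_short_read_support()].
#' @param min_reads inclusive support threshold (default 5).
#' @return list: `table` (per unique junction: `max_count`, `mean_count`,
#'   `supported`, `supported_mean`), `fraction_supported`,
#'   `fraction_supported_mean`.
#' @export
junction_support <- function(junctions, support, min_reads = 5L) {
  key <- function(d) paste(d$contig, d$start, d$end, d$strand, sep = "|")
  jn <- junctions[!duplicated(key(junctions)), , drop = FALSE]
  jk <- key(jn)
  if (nrow(support) > 0) {
    sk <- key(support)
    mx <- vapply(split(support$count, sk), max, numeric(1))
    mn <- vapply(split(support$count, sk), mean, numeric(1))
  } else {
    mx <- mn <- setNames(numeric(0), character(0))
  }
  jn$max_count <- unname(ifelse(is.na(mx[jk]), 0, mx[jk]))
  jn$mean_count <- unname(ifelse(is.na(mn[jk]), 0, mn[jk]))
  jn$supported <- jn$max_count >= min_reads
  jn$supported_mean <- jn$mean_count >= min_reads
  rownames(jn) <- NULL
  list(table = jn,
       fraction_supported = mean(jn$supported),
       fraction_supported_mean = mean(jn$supported_mean))
}

#' Short-read validation rule for one AS event
#'
#' An event is supported by short reads when it has at least one inclusion
#' read, at least one exclusion read, and at least ten reads in total
#' (all inclusive).
#'
#' @param inclusion_reads,exclusion_reads non-negative read counts
#'   consistent with the event-containing and event-lacking forms.
#' @param min_each minimal count required on each side (default 1).
#' @param min_total minimal total count (default 10).
#' @return logical flag (vectorised).
#' @export
validate_as_event <- function(inclusion_reads, exclusion_reads,
                              min_each = 1L, min_total = 10L) {
  stopifnot(all(inclusion_reads >= 0), all(exclusion_reads >= 0))
  inclusion_reads >= min_each & exclusion_reads >= min_each &
    (inclusion_reads + exclusion_reads) >= min_total
}

#' Validate IR/ES events against reference transcript models
#'
#' An IR event is validated when some reference exon fully covers the
#' retained intron; an ES event when some reference intron fully covers
#' the skipped exon. Other event types are not addressed by this rule and
#' return `NA`.
#'
#' @param event one row of an [infer_as_events()] table (or a list with
#'   `type`, `contig`, `start`, `end`).
#' @param reference list of reference [transcript_model()] objects aligned
#'   to the same genome.
#' @return `TRUE`/`FALSE` for IR and ES events, `NA` otherwise.
#' @export
validate_with_reference_transcripts <- function(event, reference) {
  if (!event$type %in% c("IR", "ES")) return(NA)
  for (m in reference) {
    if (m$contig != event$contig) next
    if (event$type == "IR") {
      if (any(contains(m$exon_start, m$exon_end, event$start, event$end))) {
        return(TRUE)
      }
    } else {
      mi <- transcript_introns(m)
      if (nrow(mi) > 0 &&
          any(contains(mi$start, mi$end, event$start, event$end))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Junction canonicity check
#'
#' When a genome is available, reports whether each junction's intron
#' starts with a canonical donor and ends with a canonical acceptor
#' dinucleotide on the coding strand (`GT..AG`, optionally `GC..AG`).
#'
#' @param junctions junction data.frame (`contig`, `start`, `end`,
#'   `strand`).
#' @param genome genome object.
#' @param allow_gc also accept the minor `GC..AG` class (default TRUE).
#' @return the table with a logical `canonical` column.
#' @export
junction_canonical <- function(junctions, genome, allow_gc = TRUE) {
  seqs <- genome_sequences(genome)
  don_ok <- c("GT", if (allow_gc) "GC")
  canon <- logical(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    s <- seqs[[junctions$contig[i]]]
    left <- substr(s, junctions$start[i], junctions$start[i] + 1L)
    right <- substr(s, junctions$end[i] - 1L, junctions$end[i])
    canon[i] <- if (junctions$strand[i] == "+") {
      left %in% don_ok && right == "AG"
    } else {
      right %in% revcomp(don_ok) && left == "CT"
    }
  }
  junctions$canonical <- canon
  junctions
}
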