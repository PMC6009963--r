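#' Plant alternative-splicing events into a gene model
#'
#' For each requested event type one new isoform is emitted that differs
#' from the reference gene model by exactly that event:
#'
#' * `IR`  - one intron retained (its flanking exons merge);
#' * `ES`  - one internal exon skipped;
#' * `A5SS` - the donor (5', in transcription direction) boundary of one
#'   intron shifted into the intron;
#' * `A3SS` - the acceptor (3') boundary shifted into the intron;
#' * `OTHER` - an isoform that starts inside the first intron (transcription
#'   direction) while sharing the remaining junctions, i.e. the
#'   "starts in an intron" flavour of the residual event class.
#'
#' Events are allocated to disjoint introns/exons so that pairwise
#' comparison of the emitted isoforms recovers the planted events and no
#' incidental ones: retained introns are exclusive to their IR event, a
#' skipped exon consumes both flanking introns (which alternative-site
#' events may still reuse), and the first intron is reserved when an
#' `OTHER` event is requested. The recorded truth coordinates are exactly
#' those [infer_as_events()] reports: the retained intron (IR), the
#' skipped exon (ES), the variable region between the two alternative
#' boundaries (A5SS/A3SS), or the intron hosting the alternative start
#' (OTHER).
#'
#' @param gene a reference [transcript_model()].
#' @param events character vector of event types, each one of
#'   `"IR"`, `"ES"`, `"A5SS"`, `"A3SS"`, `"OTHER"` (at most one `OTHER`).
#' @param shift boundary shift in bp for A5SS/A3SS events (capped below
#'   the intron length, default 12).
#' @return list with `isoforms` (the reference first, then one isoform per
#'   event) and `truth` (data.frame: isoform_id, gene_id, event_type,
#'   contig, start, end, strand).
#' @export
plant_as_isoforms <- function(gene, events, shift = 12L) {
  stopifnot(inherits(gene, "transcript_model"))
  n_ex <- length(gene$exon_start)
  intr <- transcript_introns(gene)
  n_in <- nrow(intr)
  for (ev in events) {
    if (ev %in% c("IR", "A5SS", "A3SS") && n_in < 1) {
      stop("event ", ev, " needs at least one intron; gene '", gene$id,
           "' has none")
    }
    if (ev == "ES" && n_ex < 3) {
      stop("event ES needs at least 3 exons; gene '", gene$id,
           "' has ", n_ex)
    }
    if (ev == "OTHER" && n_in < 2) {
      stop("event OTHER needs at least 2 introns; gene '", gene$id,
           "' has ", n_in)
    }
    if (!ev %in% c("IR", "ES", "A5SS", "A3SS", "OTHER")) {
      stop("unknown event type '", ev, "'")
    }
  }
  if (sum(events == "OTHER") > 1) {
    stop("at most one OTHER event can be planted per gene")
  }

  ## --- allocate disjoint targets -------------------------------------
  other_intron <- if (any(events == "OTHER")) {
    if (gene$strand == "+") 1L else n_in
  } else integer(0)
  avail <- setdiff(seq_len(n_in), other_intron)
  target <- vector("list", length(events))
  ## IR first: retained introns must not be touched by anything else
  for (k in which(events == "IR")) {
    if (length(avail) == 0) {
      stop("not enough introns in '", gene$id, "' for the requested events")
    }
    target[[k]] <- avail[1]; avail <- avail[-1]
  }
  ## ES next: the skipped exon consumes a consecutive intron pair
  es_flanks <- integer(0)
  for (k in which(events == "ES")) {
    pair <- NULL
    for (i in seq_along(avail)) {
      if ((avail[i] + 1L) %in% avail) { pair <- avail[i]; break }
    }
    if (is.null(pair)) {
      stop("not enough free internal exons in '", gene$id,
           "' for the requested ES events")
    }
    target[[k]] <- pair + 1L            # exon index between the two introns
    es_flanks <- c(es_flanks, pair, pair + 1L)
    avail <- setdiff(avail, c(pair, pair + 1L))
  }
  ## alternative-site events: fresh introns first, then ES flanks
  ass_pool <- c(avail, es_flanks)
  for (k in which(events %in% c("A5SS", "A3SS"))) {
    if (length(ass_pool) == 0) {
      stop("not enough introns in '", gene$id, "' for the requested events")
    }
    target[[k]] <- ass_pool[1]; ass_pool <- ass_pool[-1]
  }
  for (k in which(events == "OTHER")) target[[k]] <- other_intron

  ## --- emit isoforms --------------------------------------------------
  isoforms <- list(gene)
  truth <- list()
  for (k in seq_along(events)) {
    ev <- events[k]
    j <- target[[k]]
    iso_id <- sprintf("%s_%s%d", gene$id, ev, k)
    st <- gene$exon_start; en <- gene$exon_end
    if (ev == "IR") {
      st2 <- st[-(j + 1L)]
      en2 <- en[-j]
      coords <- c(intr$start[j], intr$end[j])
      iso <- transcript_model(iso_id, gene$contig, gene$strand, st2, en2,
                              gene_id = gene$gene_id)
    } else if (ev == "ES") {
      coords <- c(st[j], en[j])          # j is the skipped exon index here
      iso <- transcript_model(iso_id, gene$contig, gene$strand,
                              st[-j], en[-j], gene_id = gene$gene_id)
    } else if (ev %in% c("A5SS", "A3SS")) {
      w <- intr$end[j] - intr$start[j] + 1L
      d <- min(as.integer(shift), w - 20L)
      if (d < 2L) stop("intron ", j, " of '", gene$id,
                       "' too short to plant ", ev)
      ## donor side is the genome-left intron boundary on '+', right on '-'
      move_left <- (ev == "A5SS") == (gene$strand == "+")
      if (move_left) {
        en[j] <- en[j] + d               # left boundary shifts rightward
        coords <- c(intr$start[j], intr$start[j] + d - 1L)
      } else {
        st[j + 1L] <- st[j + 1L] - d     # right boundary shifts leftward
        coords <- c(intr$end[j] - d + 1L, intr$end[j])
      }
      iso <- transcript_model(iso_id, gene$contig, gene$strand, st, en,
                              gene_id = gene$gene_id)
    } else {                             # OTHER
      mid <- intr$start[j] + (intr$end[j] - intr$start[j]) %/% 2L
      if (gene$strand == "+") {
        st2 <- c(mid, st[-c(1L, 2L)])
        en2 <- en[-1L]
      } else {
        st2 <- st[-n_ex]
        en2 <- c(en[-c(n_ex - 1L, n_ex)], mid)
      }
      coords <- c(intr$start[j], intr$end[j])
      iso <- transcript_model(iso_id, gene$contig, gene$strand, st2, en2,
                              gene_id = gene$gene_id)
    }
    isoforms <- c(isoforms, list(iso))
    truth[[k]] <- data.frame(
      isoform_id = iso_id, gene_id = gene$gene_id, event_type = ev,
      contig = gene$contig, start = coords[1], end = coords[2],
      strand = gene$strand
    )
  }
  names(isoforms) <- vapply(isoforms, function(m) m$id, character(1))
  list(isoforms = isoforms, truth = do.call(rbind, truth))
}
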