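#' The nine transcript-versus-annotation class codes
#'
#' @return character vector of the nine codes in priority order (strongest
#'   structural evidence first).
#' @export
class_codes <- function() {
  c("STRUCT_MATCH", "NOVEL_ISOFORM", "CONTAINED_IN_CDS", "CONTAINS_GENE",
    "GENE_IN_INTRON", "INTRONIC", "SAME_STRAND_PARTIAL",
    "OPPOSITE_STRAND_OVERLAP", "NOVEL_LOCUS")
}

## group an annotation (list of transcript_model) into genes with spans
annotation_genes <- function(annotation) {
  gids <- vapply(annotation, function(m) m$gene_id, character(1))
  lapply(split(annotation, gids), function(ms) {
    sp <- vapply(ms, transcript_span, numeric(2))
    list(gene_id = ms[[1]]$gene_id, contig = ms[[1]]$contig,
         strand = ms[[1]]$strand, start = min(sp[1, ]), end = max(sp[2, ]),
         models = ms)
  })
}

#' Classify a transcript against a reference annotation
#'
#' Assigns exactly one of the nine class codes describing how the query's
#' exon-intron structure relates to the annotated genes it overlaps:
#'
#' 1. `NOVEL_LOCUS` - no genomic overlap with any annotated gene;
#' 2. `CONTAINS_GENE` - the query properly contains a whole gene;
#' 3. `INTRONIC` - the query lies inside an intron of a gene (either
#'    strand);
#' 4. `GENE_IN_INTRON` - one of the query's introns contains a whole gene;
#' 5. `STRUCT_MATCH` - identical intron chain with an annotated transcript
#'    (terminal ends free; single-exon models match by reciprocal overlap);
#' 6. `OPPOSITE_STRAND_OVERLAP` - partial exon overlap on the opposite
#'    strand;
#' 7. `SAME_STRAND_PARTIAL` - partial exon overlap on the same strand,
#'    with no shared splice junction;
#' 8. `NOVEL_ISOFORM` - shares at least one splice junction with a gene
#'    but differs at other splice sites;
#' 9. `CONTAINED_IN_CDS` - properly contained in the coding region of a
#'    gene.
#'
#' When several codes could apply, the priority order of [class_codes()]
#' decides (strongest structural evidence first), so the codes partition
#' all query/annotation configurations.
#'
#' @param query a [transcript_model()] aligned to the same genome as the
#'   annotation.
#' @param annotation list of reference [transcript_model()] objects
#'   carrying `gene_id`s.
#' @param single_exon_overlap reciprocal-overlap fraction for single-exon
#'   structure matches (default 0.5).
#' @return list: `code` (one of [class_codes()]) and `gene_id` (matched
#'   gene or `NA`).
#' @export
classify_transcript <- function(query, annotation,
                                single_exon_overlap = 0.5) {
  contigs <- unique(vapply(annotation, function(m) m$contig, character(1)))
  if (!query$contig %in% contigs) {
    stop("query contig '", query$contig, "' absent from the annotation")
  }
  qs <- transcript_span(query)
  genes <- annotation_genes(annotation)
  ov <- Filter(function(g) g$contig == query$contig &&
                 overlaps(qs[1], qs[2], g$start, g$end), genes)
  if (length(ov) == 0) return(list(code = "NOVEL_LOCUS",
                                   gene_id = NA_character_))
  qintr <- transcript_introns(query)
  qj <- paste(qintr$start, qintr$end)

  hit <- function(code, gene_id) list(code = code, gene_id = gene_id)

  ## pass 1: STRUCT_MATCH
  for (g in ov) for (m in g$models) {
    if (m$strand != query$strand) next
    if (nrow(qintr) > 0 || length(transcript_introns(m)$start) > 0) {
      if (identical_intron_chain(query, m)) return(hit("STRUCT_MATCH",
                                                       g$gene_id))
    } else {
      ms <- transcript_span(m)
      inter <- min(qs[2], ms[2]) - max(qs[1], ms[1]) + 1
      if (inter > 0 &&
          inter / (qs[2] - qs[1] + 1) >= single_exon_overlap &&
          inter / (ms[2] - ms[1] + 1) >= single_exon_overlap) {
        return(hit("STRUCT_MATCH", g$gene_id))
      }
    }
  }
  ## pass 2: NOVEL_ISOFORM (shared junction, different chain)
  if (nrow(qintr) > 0) {
    for (g in ov) for (m in g$models) {
      if (m$strand != query$strand) next
      mi <- transcript_introns(m)
      if (nrow(mi) > 0 && any(qj %in% paste(mi$start, mi$end))) {
        return(hit("NOVEL_ISOFORM", g$gene_id))
      }
    }
  }
  exon_overlap <- function(m) {
    any(outer(query$exon_start, m$exon_end, `<=`) &
          outer(query$exon_end, m$exon_start, `>=`))
  }
  ## pass 3: CONTAINED_IN_CDS - inside the coding span and touching the
  ## gene's exons (a transcript buried in an intron is INTRONIC instead)
  for (g in ov) for (m in g$models) {
    if (!is.null(m$cds) &&
        contains(m$cds[1], m$cds[2], qs[1], qs[2]) &&
        !(m$cds[1] == qs[1] && m$cds[2] == qs[2]) &&
        exon_overlap(m)) {
      return(hit("CONTAINED_IN_CDS", g$gene_id))
    }
  }
  ## pass 4: CONTAINS_GENE - the query properly contains a whole gene and
  ## meets it exonically (a gene swallowed by one query intron is the
  ## GENE_IN_INTRON case below)
  for (g in ov) {
    if (contains(qs[1], qs[2], g$start, g$end) &&
        !(qs[1] == g$start && qs[2] == g$end) &&
        any(vapply(g$models, exon_overlap, logical(1)))) {
      return(hit("CONTAINS_GENE", g$gene_id))
    }
  }
  ## pass 5: GENE_IN_INTRON (a query intron contains a whole gene)
  if (nrow(qintr) > 0) for (g in ov) {
    if (any(contains(qintr$start, qintr$end, g$start, g$end))) {
      return(hit("GENE_IN_INTRON", g$gene_id))
    }
  }
  ## pass 6: INTRONIC (query inside an intron, either strand)
  for (g in ov) for (m in g$models) {
    mi <- transcript_introns(m)
    if (nrow(mi) > 0 && any(contains(mi$start, mi$end, qs[1], qs[2]))) {
      return(hit("INTRONIC", g$gene_id))
    }
  }
  ## pass 7/8: partial exon overlap by strand
  for (g in ov) for (m in g$models) {
    if (m$strand == query$strand && exon_overlap(m)) {
      return(hit("SAME_STRAND_PARTIAL", g$gene_id))
    }
  }
  for (g in ov) for (m in g$models) {
    if (m$strand != query$strand && exon_overlap(m)) {
      return(hit("OPPOSITE_STRAND_OVERLAP", g$gene_id))
    }
  }
  ## residual: span overlap without exon overlap (straddling an intron
  ## edge-case) - fold into the partial-overlap class of the gene's strand
  g <- ov[[1]]
  if (g$strand == query$strand) hit("SAME_STRAND_PARTIAL", g$gene_id)
  else hit("OPPOSITE_STRAND_OVERLAP", g$gene_id)
}

#' Classify many transcripts against an annotation
#'
#' @param queries list of [transcript_model()] objects.
#' @inheritParams classify_transcript
#' @return data.frame: `transcript_id`, `code`, `gene_id`.
#' @export
classify_transcripts <- function(queries, annotation,
                                 single_exon_overlap = 0.5) {
  rows <- lapply(queries, function(q) {
    r <- classify_transcript(q, annotation, single_exon_overlap)
    data.frame(transcript_id = q$id, code = r$code, gene_id = r$gene_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-level difference category between matched gene models
#'
#' Compares the transcripts of one query gene with its matched reference
#' gene and assigns a single category with precedence
#' `SPAN_MULTIPLE_LOCI > SPLIT > GENE_STRUCTURE > SEQUENCE_SPAN >
#' UTR_ONLY > IDENTICAL`:
#'
#' * `SPAN_MULTIPLE_LOCI` - one query transcript spans two or more
#'   reference genes;
#' * `SPLIT` - the query transcripts form two or more non-overlapping
#'   clusters inside one reference gene;
#' * `GENE_STRUCTURE` - no query transcript shares an identical intron
#'   chain with any reference transcript (different exon-intron structure);
#' * `SEQUENCE_SPAN` - chains match but the genomic span differs and the
#'   CDS differs or is unavailable (different starting/ending exon);
#' * `UTR_ONLY` - chains match, spans differ, CDS identical;
#' * `IDENTICAL` - a chain-matching pair also agrees on its span.
#'
#' @param query_models list of the query gene's [transcript_model()]s.
#' @param ref_models list of the matched reference gene's models.
#' @param all_ref_genes optional full annotation (list of models) used to
#'   detect `SPAN_MULTIPLE_LOCI`; defaults to `ref_models` only.
#' @return category string.
#' @export
classify_gene_difference <- function(query_models, ref_models,
                                     all_ref_genes = NULL) {
  genes <- annotation_genes(all_ref_genes %||% ref_models)
  ref_gene <- annotation_genes(ref_models)[[1]]
  qs <- vapply(query_models, transcript_span, numeric(2))
  any_overlap <- any(vapply(query_models, function(q) {
    s <- transcript_span(q)
    q$contig == ref_gene$contig &&
      overlaps(s[1], s[2], ref_gene$start, ref_gene$end)
  }, logical(1)))
  if (!any_overlap) {
    stop("query gene does not overlap the reference gene ",
         "(should have been NOVEL_LOCUS upstream)")
  }
  ## one query transcript covering >= 2 reference genes?
  for (q in query_models) {
    s <- transcript_span(q)
    n_hit <- sum(vapply(genes, function(g) {
      g$contig == q$contig && overlaps(s[1], s[2], g$start, g$end)
    }, logical(1)))
    if (n_hit >= 2) return("SPAN_MULTIPLE_LOCI")
  }
  ## multiple non-overlapping query clusters in the reference gene?
  o <- order(qs[1, ])
  clusters <- 1L
  right <- qs[2, o[1]]
  for (i in seq_along(o)[-1]) {
    if (qs[1, o[i]] > right) clusters <- clusters + 1L
    right <- max(right, qs[2, o[i]])
  }
  if (clusters >= 2) return("SPLIT")
  ## best pair with identical intron chain
  for (q in query_models) for (m in ref_gene$models) {
    if (q$strand == m$strand && identical_intron_chain(q, m)) {
      sq <- transcript_span(q); sm <- transcript_span(m)
      if (all(sq == sm)) return("IDENTICAL")
      if (!is.null(q$cds) && !is.null(m$cds) && all(q$cds == m$cds)) {
        return("UTR_ONLY")
      }
      return("SEQUENCE_SPAN")
    }
  }
  "GENE_STRUCTURE"
}

#' Collapse redundant transcripts into unique isoforms
#'
#' Spliced transcripts with identical intron chains merge into one isoform
#' whose terminal ends are the outermost observed ends. Single-exon
#' transcripts on the same contig and strand merge transitively when they
#' reciprocally overlap by at least `single_exon_overlap`. A merged isoform
#' is full-length iff any member is (the "FL-assembly" convention).
#'
#' @param models list of [transcript_model()] objects (reads as aligned).
#' @param is_fl optional logical vector, one flag per model.
#' @param single_exon_overlap reciprocal-overlap merge threshold for
#'   single-exon models (default 0.5).
#' @return list: `isoforms` (list of merged [transcript_model()]s, ids
#'   `iso_001`, ...), `is_fl` (per isoform), `members` (data.frame mapping
#'   every input id to its output isoform id).
#' @export
collapse_transcripts <- function(models, is_fl = NULL,
                                 single_exon_overlap = 0.5) {
  n <- length(models)
  if (n == 0) {
    return(list(isoforms = list(), is_fl = logical(0),
                members = data.frame(input_id = character(0),
                                     isoform_id = character(0))))
  }
  is_fl <- is_fl %||% rep(FALSE, n)
  spliced <- vapply(models, function(m) length(m$exon_start) > 1, logical(1))
  group <- character(n)
  group[spliced] <- vapply(models[spliced], intron_chain_key, character(1))
  ## transitive reciprocal-overlap clustering of single-exon models
  se_idx <- which(!spliced)
  if (length(se_idx)) {
    parent <- seq_along(se_idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    sp <- vapply(models[se_idx], transcript_span, numeric(2))
    key <- paste(vapply(models[se_idx], function(m) m$contig, character(1)),
                 vapply(models[se_idx], function(m) m$strand, character(1)))
    for (i in seq_along(se_idx)) for (j in seq_len(i - 1)) {
      if (key[i] != key[j]) next
      inter <- min(sp[2, i], sp[2, j]) - max(sp[1, i], sp[1, j]) + 1
      if (inter <= 0) next
      wi <- sp[2, i] - sp[1, i] + 1; wj <- sp[2, j] - sp[1, j] + 1
      if (inter / wi >= single_exon_overlap &&
          inter / wj >= single_exon_overlap) {
        parent[find(i)] <- find(j)
      }
    }
    roots <- vapply(seq_along(se_idx), find, integer(1))
    group[se_idx] <- paste0("SE:", key, ":", roots)
  }
  ids <- vapply(models, function(m) m$id, character(1))
  merged <- list(); merged_fl <- logical(0); members <- list()
  grp_order <- unique(group[order(
    vapply(models, function(m) m$contig, character(1)),
    vapply(models, function(m) transcript_span(m)[1], numeric(1)))])
  for (gi in seq_along(grp_order)) {
    idx <- which(group == grp_order[gi])
    ms <- models[idx]
    iso_id <- sprintf("iso_%03d", gi)
    first <- ms[[1]]
    st <- first$exon_start; en <- first$exon_end
    ## widen the terminal exons to the outermost observed ends
    st[1] <- min(vapply(ms, function(m) m$exon_start[1], numeric(1)))
    k <- length(en)
    en[k] <- max(vapply(ms, function(m) m$exon_end[length(m$exon_end)],
                        numeric(1)))
    merged[[iso_id]] <- transcript_model(iso_id, first$contig, first$strand,
                                         st, en, gene_id = first$gene_id)
    merged_fl[iso_id] <- any(is_fl[idx])
    members[[iso_id]] <- data.frame(input_id = ids[idx], isoform_id = iso_id)
  }
  list(isoforms = merged, is_fl = merged_fl,
       members = {
         m <- do.call(rbind, members); rownames(m) <- NULL; m
       })
}

#' Remove short transcripts
#'
#' Drops isoforms whose spliced length is below `min_len` (strictly), the
#' minimum-transcript-length convention of draft annotations.
#'
#' @param models list of [transcript_model()] objects.
#' @param min_len minimal spliced length kept (default 100; a 100 bp model
#'   is kept, 99 bp is removed).
#' @return the kept models.
#' @export
remove_short_transcripts <- function(models, min_len = 100L) {
  keep <- vapply(models, transcript_spliced_length, numeric(1)) >= min_len
  models[keep]
}
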