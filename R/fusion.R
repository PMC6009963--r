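#' Call a fusion transcript from one read's split alignment
#'
#' A read is a fusion candidate when its alignment splits across distinct
#' loci and all four criteria hold: (1) at least two distinct loci; (2)
#' every locus carries at least `min_frac` of the read; (3) the combined
#' aligned coverage is at least `min_combined` of the read; (4) same-contig
#' loci are at least `min_distance` apart. Same-contig segments closer than
#' `min_distance` are first merged into one locus (they do not count as
#' distinct), which is how criterion (4) rejects nearby split alignments.
#'
#' @param segments data.frame of one read's alignment segments: `contig`,
#'   `start`, `end`, `strand`, plus either `frac` (fraction of the read
#'   aligned in the segment) or `L` and `read_len` from which it is
#'   computed. Optional `read_start`/`read_end` columns are checked for
#'   overlapping read intervals.
#' @param transcript_id id recorded on the call (defaults to the segment
#'   table's `read_id` if present).
#' @param min_frac minimal per-locus read fraction (default 0.05).
#' @param min_combined minimal combined read coverage (default 0.85).
#' @param min_distance minimal genomic separation of same-contig loci in bp
#'   (default 100000).
#' @return A `fusion_call` object, or `NULL` with attribute `"reason"`
#'   naming the violated criterion (`"locus_distance"`,
#'   `"single_locus"`, `"segment_fraction"`, `"combined_coverage"`).
#' @export
call_fusion <- function(segments, transcript_id = NULL,
                        min_frac = 0.05, min_combined = 0.85,
                        min_distance = 100000L) {
  fusion_eval(segments, transcript_id, min_frac, min_combined,
              min_distance)$call
}

## worker shared by call_fusion() and fusion_calls(); also reports which
## criterion rejected a non-call, for post-hoc audits
fusion_eval <- function(segments, transcript_id = NULL,
                        min_frac = 0.05, min_combined = 0.85,
                        min_distance = 100000L) {
  transcript_id <- transcript_id %||% segments$read_id[1] %||% "read"
  if (is.null(segments$frac)) {
    if (is.null(segments$L) || is.null(segments$read_len)) {
      stop("segments need 'frac' or both 'L' and 'read_len'")
    }
    segments$frac <- segments$L / segments$read_len
  }
  if (!is.null(segments$read_start)) {
    o <- order(segments$read_start)
    rs <- segments$read_start[o]; re <- segments$read_end[o]
    if (length(rs) > 1 && any(rs[-1] <= re[-length(re)])) {
      stop("overlapping read segments in '", transcript_id, "'")
    }
  }
  loci <- merge_nearby_segments(segments, min_distance)
  merged_any <- nrow(loci) < nrow(segments)
  if (nrow(loci) < 2) {
    return(list(call = NULL,
                reason = if (merged_any) "locus_distance" else
                  "single_locus"))
  }
  if (any(loci$frac < min_frac)) {
    return(list(call = NULL, reason = "segment_fraction"))
  }
  combined <- sum(loci$frac)
  if (combined < min_combined) {
    return(list(call = NULL, reason = "combined_coverage"))
  }
  o <- order(loci$contig, loci$start)
  loci <- loci[o, , drop = FALSE]
  rownames(loci) <- NULL
  call <- structure(
    list(transcript_id = transcript_id, loci = loci,
         combined_coverage = combined,
         read_len = segments$read_len[1] %||% NA_integer_),
    class = "fusion_call"
  )
  list(call = call, reason = "")
}

## transitively merge same-contig segments whose genomic gap is below
## min_distance; each resulting row is one locus
merge_nearby_segments <- function(segments, min_distance) {
  segments <- segments[order(segments$contig, segments$start), , drop = FALSE]
  grp <- integer(nrow(segments))
  g <- 0L
  for (i in seq_len(nrow(segments))) {
    if (i == 1 || segments$contig[i] != segments$contig[i - 1] ||
        segments$start[i] - segments$end[i - 1] >= min_distance) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  out <- do.call(rbind, lapply(split(segments, grp), function(s) {
    data.frame(contig = s$contig[1], start = min(s$start),
               end = max(s$end), strand = s$strand[1],
               frac = sum(s$frac))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.fusion_call <- function(x, ...) {
  cat(sprintf("<fusion_call> %s: %d loci, combined coverage %.2f\n",
              x$transcript_id, nrow(x$loci), x$combined_coverage))
  invisible(x)
}

#' Call fusions over a whole alignment table
#'
#' Splits a segment table by read and applies [call_fusion()] to each;
#' reads with a single alignment row are trivially not fusions.
#'
#' @param alns alignment table with a `read_id` column (e.g. from
#'   [alignments_from_truth()] or SAM import).
#' @inheritParams call_fusion
#' @return list: `calls` (list of `fusion_call`), `audit` (data.frame
#'   `read_id`, `called`, `reason`).
#' @export
fusion_calls <- function(alns, min_frac = 0.05, min_combined = 0.85,
                         min_distance = 100000L) {
  by_read <- split(as.data.frame(alns), alns$read_id)
  calls <- list(); audit <- list()
  for (id in names(by_read)) {
    ev <- fusion_eval(by_read[[id]], transcript_id = id,
                      min_frac = min_frac, min_combined = min_combined,
                      min_distance = min_distance)
    if (is.null(ev$call)) {
      audit[[id]] <- data.frame(read_id = id, called = FALSE,
                                reason = ev$reason)
    } else {
      calls[[id]] <- ev$call
      audit[[id]] <- data.frame(read_id = id, called = TRUE, reason = "")
    }
  }
  audit <- do.call(rbind, audit)
  rownames(audit) <- NULL
  list(calls = calls, audit = audit)
}

call_boundaries <- function(call) {
  as.numeric(t(as.matrix(call$loci[, c("start", "end")])))
}

call_signature <- function(call) {
  paste(nrow(call$loci), paste(call$loci$contig, collapse = ","), sep = "|")
}

#' Deduplicate fusion calls by alignment boundaries
#'
#' Calls whose loci lie on the same contigs and whose corresponding
#' segment boundaries all agree within `tolerance` bp form one group;
#' one representative per group is kept - the call with the greatest read
#' length, ties broken by lexicographically smallest transcript id. The
#' result is invariant to input order.
#'
#' @param calls list of `fusion_call` objects.
#' @param tolerance boundary agreement tolerance in bp (default 50).
#' @return list of representative `fusion_call` objects, each with a
#'   `group_size` field.
#' @export
group_by_boundaries <- function(calls, tolerance = 50L) {
  if (length(calls) == 0) return(list())
  sig <- vapply(calls, call_signature, character(1))
  ids <- vapply(calls, function(x) x$transcript_id, character(1))
  bnd <- lapply(calls, call_boundaries)
  ## deterministic order: signature, then boundary vector, then id
  key <- vapply(bnd, function(b) paste(sprintf("%012.0f", b), collapse = ","),
                character(1))
  o <- order(sig, key, ids)
  calls <- calls[o]; sig <- sig[o]; bnd <- bnd[o]; ids <- ids[o]
  reps <- list()
  leaders <- list()   # per cluster: list(sig, boundaries)
  members <- list()
  for (i in seq_along(calls)) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (leaders[[k]]$sig == sig[i] &&
          all(abs(leaders[[k]]$bnd - bnd[[i]]) <= tolerance)) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders[[length(leaders) + 1L]] <- list(sig = sig[i], bnd = bnd[[i]])
      members[[length(members) + 1L]] <- i
    }
  }
  for (k in seq_along(members)) {
    grp <- calls[members[[k]]]
    len <- vapply(grp, function(x) as.numeric(x$read_len %||% NA), numeric(1))
    len[is.na(len)] <- -Inf
    gid <- vapply(grp, function(x) x$transcript_id, character(1))
    best <- order(-len, gid)[1]
    rep <- grp[[best]]
    rep$group_size <- length(grp)
    reps[[length(reps) + 1L]] <- rep
  }
  reps
}

#' Classify a fusion call's genomic span
#'
#' `inter_chromosomal` when the loci lie on different contigs, otherwise
#' `intra_chromosomal`. Inter-contig calls additionally get a subtype from
#' the contig naming (`chromosome_chromosome`, `chromosome_scaffold` or
#' `scaffold_scaffold`), mirroring the breakdown used for draft assemblies
#' that mix chromosome-scale sequences and unplaced scaffolds.
#'
#' @param call a `fusion_call`.
#' @param scaffold_pattern regular expression identifying scaffold-like
#'   contig names (default `"^scaf"`).
#' @return the call with `span_class` and (for inter calls) `span_subtype`
#'   fields set.
#' @export
classify_span <- function(call, scaffold_pattern = "^scaf") {
  stopifnot(nrow(call$loci) >= 2)
  ctg <- call$loci$contig
  if (length(unique(ctg)) == 1) {
    call$span_class <- "intra_chromosomal"
    call$span_subtype <- NA_character_
  } else {
    call$span_class <- "inter_chromosomal"
    is_scaf <- grepl(scaffold_pattern, ctg, ignore.case = TRUE)
    n_scaf <- sum(is_scaf[!duplicated(ctg)])
    call$span_subtype <- if (n_scaf == 0) "chromosome_chromosome"
      else if (n_scaf == length(unique(ctg))) "scaffold_scaffold"
      else "chromosome_scaffold"
  }
  call
}

locus_key <- function(contig, pos, bin_width) {
  paste(contig, (as.numeric(pos) - 1) %/% bin_width, sep = ":")
}

call_locus_keys <- function(call, bin_width) {
  locus_key(call$loci$contig, (call$loci$start + call$loci$end) / 2,
            bin_width)
}

unordered_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

#' Validate fusion calls with paired short-read locus links
#'
#' Loci are keyed by `(contig, genomic bin)` of their midpoints; a call is
#' validated when every pair of its loci is linked by at least `min_pairs`
#' read pairs in the link table. The supporting count recorded on the call
#' is the minimum over its locus pairs.
#'
#' @param calls list of `fusion_call` objects.
#' @param links data.frame of locus links: `contig_a`, `pos_a`, `contig_b`,
#'   `pos_b`, `n_pairs` (see [make_locus_links()]).
#' @param min_pairs inclusive validation threshold (default 5).
#' @param bin_width locus bin width in bp used to match link positions to
#'   call segments (default 10000).
#' @return the calls with `validated` and `n_supporting_pairs` fields set.
#' @export
validate_with_pairs <- function(calls, links, min_pairs = 5L,
                                bin_width = 10000L) {
  tab <- if (is.null(links) || nrow(links) == 0) {
    setNames(numeric(0), character(0))
  } else {
    k <- unordered_pair_key(locus_key(links$contig_a, links$pos_a, bin_width),
                            locus_key(links$contig_b, links$pos_b, bin_width))
    tapply(links$n_pairs, k, sum)
  }
  lapply(calls, function(call) {
    keys <- call_locus_keys(call, bin_width)
    pairs <- utils::combn(keys, 2)
    support <- vapply(seq_len(ncol(pairs)), function(j) {
      v <- tab[unordered_pair_key(pairs[1, j], pairs[2, j])]
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))
    call$n_supporting_pairs <- min(support)
    call$validated <- call$n_supporting_pairs >= min_pairs
    call
  })
}

#' Unique genomic locus pairs covered by fusion calls
#'
#' @param calls list of (deduplicated) `fusion_call` objects.
#' @param bin_width locus bin width in bp (default 10000).
#' @return data.frame: `pair`, `n_calls`, `n_validated` (NA when calls have
#'   not been validated).
#' @export
unique_locus_pairs <- function(calls, bin_width = 10000L) {
  if (length(calls) == 0) {
    return(data.frame(pair = character(0), n_calls = integer(0),
                      n_validated = integer(0)))
  }
  rows <- lapply(calls, function(call) {
    keys <- call_locus_keys(call, bin_width)
    pairs <- utils::combn(keys, 2)
    data.frame(pair = unordered_pair_key(pairs[1, ], pairs[2, ]),
               validated = if (is.null(call$validated)) NA else
                 call$validated)
  })
  tab <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(tab, tab$pair), function(s) {
    data.frame(pair = s$pair[1], n_calls = nrow(s),
               n_validated = if (all(is.na(s$validated))) NA_integer_
                 else sum(s$validated, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Fusion calls as a BEDPE-like table
#'
#' Two-locus calls become one row each with both genomic intervals plus the
#' span class and validation columns.
#'
#' @param calls list of `fusion_call` objects.
#' @return data.frame in BEDPE-like layout.
#' @export
calls_to_bedpe <- function(calls) {
  rows <- lapply(calls, function(call) {
    l <- call$loci
    data.frame(
      contig_a = l$contig[1], start_a = l$start[1], end_a = l$end[1],
      contig_b = l$contig[2], start_b = l$start[2], end_b = l$end[2],
      transcript_id = call$transcript_id,
      span_class = call$span_class %||% NA_character_,
      n_pairs = call$n_supporting_pairs %||% NA_real_,
      validated = call$validated %||% NA
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
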