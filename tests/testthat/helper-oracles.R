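# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results from first principles rather than
# calling the implementation paths they check.

# exhaustive codon-walk ORF scanner: try every position, walk to a stop
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  if (n < 6) return(best)
  for (i in seq_len(n - 5)) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      cod <- substr(seq, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2 - i + 1)
        break
      }
      j <- j + 3
    }
  }
  as.integer(best)
}

# independent pairwise AS-event enumerator over explicit interval tables
oracle_as_events <- function(isoforms) {
  evs <- list()
  put <- function(type, s, e) {
    evs[[paste(type, s, e)]] <<- data.frame(type = type, start = s, end = e)
  }
  strand <- isoforms[[1]]$strand
  n <- length(isoforms)
  for (ai in seq_len(n)) for (bi in seq_len(n)) {
    if (ai == bi) next
    A <- isoforms[[ai]]; B <- isoforms[[bi]]
    Aex <- cbind(A$exon_start, A$exon_end)
    Bex <- cbind(B$exon_start, B$exon_end)
    Ain <- transcript_introns(A)
    Bin <- transcript_introns(B)
    if (nrow(Bin)) {
      for (ei in seq_len(nrow(Aex))) for (ii in seq_len(nrow(Bin))) {
        if (Aex[ei, 1] < Bin$start[ii] && Aex[ei, 2] > Bin$end[ii]) {
          put("IR", Bin$start[ii], Bin$end[ii])
        }
      }
      if (nrow(Aex) >= 3) {
        for (ei in 2:(nrow(Aex) - 1)) for (ii in seq_len(nrow(Bin))) {
          if (Bin$start[ii] < Aex[ei, 1] && Bin$end[ii] > Aex[ei, 2]) {
            put("ES", Aex[ei, 1], Aex[ei, 2])
          }
        }
      }
    }
    if (nrow(Ain) && nrow(Bin)) {
      for (ii in seq_len(nrow(Ain))) for (jj in seq_len(nrow(Bin))) {
        sl <- Ain$start[ii] == Bin$start[jj]
        sr <- Ain$end[ii] == Bin$end[jj]
        if (sl + sr != 1) next
        lo <- min(Ain$start[ii], Bin$start[jj])
        hi <- max(Ain$end[ii], Bin$end[jj])
        allex <- rbind(Aex, Bex)
        if (any(allex[, 1] > lo & allex[, 2] < hi)) next
        if (sl) {
          put(if (strand == "+") "A3SS" else "A5SS",
              min(Ain$end[ii], Bin$end[jj]) + 1L, hi)
        } else {
          put(if (strand == "+") "A5SS" else "A3SS",
              lo, max(Ain$start[ii], Bin$start[jj]) - 1L)
        }
      }
      shared <- any(paste(Ain$start, Ain$end) %in%
                      paste(Bin$start, Bin$end))
      if (shared) {
        for (bnd in c(min(Aex), max(Aex))) {
          for (ii in seq_len(nrow(Bin))) {
            if (Bin$start[ii] < bnd && Bin$end[ii] > bnd) {
              put("OTHER", Bin$start[ii], Bin$end[ii])
            }
          }
        }
      }
    }
  }
  if (!length(evs)) {
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0)))
  }
  out <- do.call(rbind, evs)
  out <- out[order(out$type, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# event tables as comparable key strings
event_keys <- function(ev) sort(paste(ev$type, ev$start, ev$end))

# deterministic multi-exon gene fixture
make_gene <- function(id = "g1", contig = "chr1", strand = "+",
                      n_exons = 4, start = 1000, exon_w = 150,
                      intron_w = 120, gene_id = id) {
  st <- integer(n_exons); en <- integer(n_exons)
  pos <- start
  for (i in seq_len(n_exons)) {
    st[i] <- pos
    en[i] <- pos + exon_w - 1L
    pos <- en[i] + intron_w + 1L
  }
  transcript_model(id, contig, strand, st, en, gene_id = gene_id)
}

# random gene with valid random planted events; returns the isoform list
random_event_fixture <- function() {
  n_exons <- sample(3:7, 1)
  strand <- sample(c("+", "-"), 1)
  gene <- make_gene("rg.t1", "chr1", strand, n_exons,
                    start = sample(500:2000, 1),
                    exon_w = sample(80:200, 1),
                    intron_w = sample(60:150, 1))
  n_in <- n_exons - 1L
  pool <- c(
    rep("IR", max(0, n_in - 1)),
    if (n_exons >= 3) "ES",
    rep(c("A5SS", "A3SS"), 2),
    if (n_in >= 2) "OTHER"
  )
  k <- sample(1:min(3, length(pool)), 1)
  events <- sample(pool, k)
  # respect the allocator's capacity: IR slots + ES pairs + OTHER reserve
  need <- sum(events == "IR") + 2 * sum(events == "ES") +
    sum(events == "OTHER")
  if (need > n_in) return(NULL)
  tryCatch(plant_as_isoforms(gene, events), error = function(e) NULL)
}
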