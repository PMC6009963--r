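test_that("genome generation honours size, determinism and GC content", {
  g <- generate_genome(1, 10000, gc = 0.5, seed = 7)
  s <- genome_sequences(g)
  expect_length(s, 1)
  expect_equal(nchar(s[[1]]), 10000)

  g2 <- generate_genome(1, 10000, gc = 0.5, seed = 7)
  expect_identical(genome_sequences(g2), s)

  g3 <- generate_genome(3, 5000, gc = 0.3, seed = 1)
  bases <- strsplit(paste(unlist(genome_sequences(g3)), collapse = ""),
                    "")[[1]]
  gc_obs <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.30), 0.03)

  expect_error(generate_genome(0, 10000), "n_contigs")
  expect_error(generate_genome(1, 500), "contig_length")
  expect_error(generate_genome(1, 10000, gc = 1.2), "gc")
})

test_that("gene models are placed without overlap and splice sites are canonical", {
  g <- generate_genome(2, 50000, seed = 11)
  gm <- generate_gene_models(g, 10, exons_per_gene = c(3, 5), seed = 12)
  expect_length(gm$models, 10)
  n_ex <- vapply(gm$models, function(m) length(m$exon_start), integer(1))
  expect_true(all(n_ex >= 3 & n_ex <= 5))

  # non-overlap per contig
  spans <- data.frame(
    contig = vapply(gm$models, function(m) m$contig, character(1)),
    t(vapply(gm$models, transcript_span, numeric(2)))
  )
  for (ctg in unique(spans$contig)) {
    s <- spans[spans$contig == ctg, ]
    s <- s[order(s$X1), ]
    if (nrow(s) > 1) expect_true(all(s$X1[-1] > s$X2[-nrow(s)]))
  }

  # every intron starts GT and ends AG on the coding strand
  expect_equal(canonical_splice_fraction(gm$models, gm$genome), 1.0)

  # single-exon genes emit no splice sites
  gm1 <- generate_gene_models(generate_genome(1, 20000, seed = 3), 3,
                              exons_per_gene = c(1, 1), seed = 4)
  expect_true(all(vapply(gm1$models, function(m)
    nrow(transcript_introns(m)) == 0, logical(1))))

  expect_error(
    generate_gene_models(generate_genome(1, 1200, seed = 5), 50, seed = 6),
    "cannot place"
  )
})

test_that("planted AS isoforms match their textbook definitions", {
  g3 <- make_gene("g3.t1", n_exons = 3)
  es <- plant_as_isoforms(g3, "ES")
  iso <- es$isoforms[[2]]
  expect_length(iso$exon_start, 2)
  expect_identical(iso$exon_start, g3$exon_start[c(1, 3)])
  expect_identical(iso$exon_end, g3$exon_end[c(1, 3)])

  g2 <- make_gene("g2.t1", n_exons = 2)
  ir <- plant_as_isoforms(g2, "IR")
  iso <- ir$isoforms[[2]]
  expect_length(iso$exon_start, 1)
  expect_equal(transcript_span(iso), transcript_span(g2))

  expect_error(plant_as_isoforms(make_gene("s", n_exons = 1), "IR"), "IR")
  expect_error(plant_as_isoforms(g2, "ES"), "ES")
  expect_error(plant_as_isoforms(g2, "OTHER"), "OTHER")
})

test_that("multi-event planting round-trips through the AS caller", {
  gene <- make_gene("g4.t1", n_exons = 4)
  pl <- plant_as_isoforms(gene, c("IR", "ES", "A5SS"))
  expect_length(pl$isoforms, 4)
  ev <- infer_as_events(pl$isoforms)
  expect_setequal(ev$type, c("IR", "ES", "A5SS"))
  expect_identical(event_keys(ev),
                   event_keys(data.frame(type = pl$truth$event_type,
                                         start = pl$truth$start,
                                         end = pl$truth$end)))
})

test_that("noiseless reads reproduce decorated isoform sequences exactly", {
  g <- generate_genome(1, 30000, seed = 21)
  gm <- generate_gene_models(g, 4, seed = 22)
  sim <- simulate_long_reads(gm$models, gm$genome, reads_per_isoform = 2,
                             p = 0, fl_fraction = 1, rc_fraction = 0,
                             seed = 23)
  pr <- default_primers()
  iso_by_id <- setNames(gm$models,
                        vapply(gm$models, function(m) m$id, character(1)))
  for (i in seq_len(nrow(sim$truth))) {
    src <- iso_by_id[[sim$truth$source_isoform[i]]]
    expected <- paste0(pr$p5, transcript_sequence(src, gm$genome),
                       strrep("A", 30), pr$p3)
    expect_identical(unname(sim$reads[[sim$truth$read_id[i]]]), expected)
  }
  expect_error(simulate_long_reads(list(), gm$genome), "empty")
})

test_that("per-read error counts follow the binomial error model", {
  g <- generate_genome(1, 30000, seed = 31)
  gm <- generate_gene_models(g, 1, exons_per_gene = c(5, 5),
                             exon_len = c(380, 420), seed = 32)
  iso_len <- transcript_spliced_length(gm$models[[1]])
  p <- 0.05
  sim <- simulate_long_reads(gm$models, gm$genome, reads_per_isoform = 120,
                             p = p, fl_fraction = 1, rc_fraction = 0,
                             seed = 33)
  # planted error counts: mean within 3 binomial sd of n*p over read length
  n_dec <- nchar(sim$reads[1]) # decorated length varies by +-indels only
  L <- mean(sim$truth$read_len)
  expect_lt(abs(mean(sim$truth$n_errors) - L * p),
            3 * sqrt(L * p * (1 - p) / nrow(sim$truth)))
  # realised edit distance to the truth agrees with the planted counts
  aln <- alignments_from_truth(sim, gm$models, gm$genome)
  expect_lt(abs(mean(aln$K) - mean(sim$truth$n_errors)),
            0.1 * mean(sim$truth$n_errors))
})

test_that("fusion reads concatenate the two planted loci", {
  g <- generate_genome(2, 30000, seed = 41)
  gm <- generate_gene_models(g, 6, seed = 42)
  ids <- names(gm$models)
  fs <- data.frame(
    isoform_a = vapply(gm$models[ids[c(1, 3, 5)]], function(m) m$id, ""),
    isoform_b = vapply(gm$models[ids[c(2, 4, 6)]], function(m) m$id, "")
  )
  sim <- simulate_long_reads(gm$models, gm$genome,
                             reads_per_isoform = 1, p = 0, fl_fraction = 1,
                             fusion_spec = fs, rc_fraction = 0, seed = 43)
  expect_equal(sum(sim$truth$kind == "fusion"), 3)
  expect_equal(nrow(sim$fusion_truth), 3)
  pr <- default_primers()
  iso_by_id <- setNames(gm$models,
                        vapply(gm$models, function(m) m$id, character(1)))
  for (i in seq_len(nrow(fs))) {
    rid <- sim$fusion_truth$read_id[i]
    a <- sim$fusion_truth[i, ]
    expected <- paste0(
      pr$p5,
      transcript_sequence(iso_by_id[[fs$isoform_a[i]]], gm$genome),
      transcript_sequence(iso_by_id[[fs$isoform_b[i]]], gm$genome),
      strrep("A", 30), pr$p3
    )
    expect_identical(unname(sim$reads[[rid]]), expected)
    expect_gte(a$frac_a, 0.05)
    expect_gte(a$frac_b, 0.05)
  }
})

test_that("junction support counts sum isoform depths", {
  isos <- list(
    transcript_model("a", "c", "+", c(1, 101, 201), c(50, 150, 250)),
    transcript_model("b", "c", "+", c(1, 201), c(50, 250))
  )
  sup <- simulate_short_read_support(isos, depth = c(10, 20))
  # junction shared by nothing: isoform a's two junctions at 10, b's at 20
  expect_equal(sort(sup$count), c(10, 10, 20))

  sup0 <- simulate_short_read_support(isos, depth = 0)
  expect_true(all(sup0$count == 0))

  one <- simulate_short_read_support(isos[1], depth = 50)
  expect_true(all(one$count == 50))

  # a junction present in both isoforms accumulates both depths
  isos2 <- list(
    transcript_model("a", "c", "+", c(1, 101), c(50, 150)),
    transcript_model("b", "c", "+", c(1, 101, 201), c(50, 150, 250))
  )
  sup2 <- simulate_short_read_support(isos2, depth = c(10, 20))
  shared <- sup2[sup2$start == 51 & sup2$end == 100, ]
  expect_equal(shared$count, 30)
})

test_that("generators are bit-reproducible under a fixed seed", {
  g <- generate_genome(2, 20000, seed = 51)
  gm <- generate_gene_models(g, 5, seed = 52)
  s1 <- simulate_long_reads(gm$models, gm$genome, reads_per_isoform = 3,
                            p = 0.03, seed = 53)
  g2 <- generate_genome(2, 20000, seed = 51)
  gm2 <- generate_gene_models(g2, 5, seed = 52)
  s2 <- simulate_long_reads(gm2$models, gm2$genome, reads_per_isoform = 3,
                            p = 0.03, seed = 53)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})
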