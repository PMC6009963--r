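# shared reference annotation: a 3-exon plus-strand gene with a CDS and a
# 2-exon minus-strand gene
ref_ann <- list(
  transcript_model("ref1.t1", "chr1", "+", c(1000, 1500, 2000),
                   c(1200, 1700, 2300), gene_id = "ref1",
                   cds = c(1050, 2250)),
  transcript_model("ref2.t1", "chr1", "-", c(9000, 9500), c(9200, 9800),
                   gene_id = "ref2")
)

test_that("each of the nine classes is assigned to its hand-built fixture", {
  fixture <- list(
    STRUCT_MATCH = transcript_model("q1", "chr1", "+",
                                    c(950, 1500, 2000),
                                    c(1200, 1700, 2400)),
    NOVEL_ISOFORM = transcript_model("q2", "chr1", "+", c(1000, 1500),
                                     c(1200, 1750)),
    CONTAINED_IN_CDS = transcript_model("q3", "chr1", "+", 1100, 1150),
    CONTAINS_GENE = transcript_model("q4", "chr1", "+", 900, 2500),
    GENE_IN_INTRON = transcript_model("q5", "chr1", "+",
                                      c(8000, 10000), c(8500, 10500)),
    INTRONIC = transcript_model("q6", "chr1", "-", 1720, 1980),
    SAME_STRAND_PARTIAL = transcript_model("q7", "chr1", "+", 2200, 2600),
    OPPOSITE_STRAND_OVERLAP = transcript_model("q8", "chr1", "+",
                                               9100, 9300),
    NOVEL_LOCUS = transcript_model("q9", "chr1", "+", 50000, 50500)
  )
  for (code in names(fixture)) {
    expect_equal(classify_transcript(fixture[[code]], ref_ann)$code, code,
                 label = code)
  }
  expect_error(classify_transcript(
    transcript_model("qx", "chrZ", "+", 1, 100), ref_ann), "contig")
})

test_that("random layouts always receive exactly one valid code", {
  set.seed(42)
  n_ok <- 0
  for (i in 1:400) {
    n <- sample(1:4, 1)
    st <- sort(sample(seq(100, 40000, by = 10), n))
    en <- st + sample(50:400, n, replace = TRUE)
    if (n > 1 && any(st[-1] <= en[-n] + 1)) next
    q <- transcript_model("qz", "chr1", sample(c("+", "-"), 1), st, en)
    r <- classify_transcript(q, ref_ann)
    expect_length(r$code, 1)
    expect_true(r$code %in% class_codes())
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 200)
})

test_that("structural match is symmetric in query and reference", {
  a <- transcript_model("a", "chr1", "+", c(900, 1500, 2000),
                        c(1200, 1700, 2500), gene_id = "ga")
  b <- ref_ann[[1]]
  expect_equal(classify_transcript(a, list(b))$code, "STRUCT_MATCH")
  expect_equal(classify_transcript(b, list(a))$code, "STRUCT_MATCH")
})

test_that("gene-difference categories follow the stated precedence", {
  ref <- list(transcript_model("r.t1", "chr1", "+", c(1000, 1500, 2000),
                               c(1200, 1700, 2300), gene_id = "r",
                               cds = c(1050, 2250)))
  # identical chain, longer 3' terminal exon, CDS unchanged -> UTR_ONLY
  utr <- transcript_model("q.t1", "chr1", "+", c(1000, 1500, 2000),
                          c(1200, 1700, 2600), gene_id = "q",
                          cds = c(1050, 2250))
  expect_equal(classify_gene_difference(list(utr), ref), "UTR_ONLY")

  # same ends, CDS differs -> SEQUENCE_SPAN
  span <- transcript_model("q.t2", "chr1", "+", c(900, 1500, 2000),
                           c(1200, 1700, 2600), gene_id = "q",
                           cds = c(950, 2250))
  expect_equal(classify_gene_difference(list(span), ref), "SEQUENCE_SPAN")

  # internal exon absent, other junctions shared -> GENE_STRUCTURE
  struct <- transcript_model("q.t3", "chr1", "+", c(1000, 2000),
                             c(1200, 2300), gene_id = "q")
  expect_equal(classify_gene_difference(list(struct), ref),
               "GENE_STRUCTURE")

  # one transcript spanning two reference genes -> SPAN_MULTIPLE_LOCI
  two_genes <- c(ref, list(transcript_model("r2.t1", "chr1", "+",
                                            c(5000, 5500), c(5200, 5800),
                                            gene_id = "r2")))
  wide <- transcript_model("q.t4", "chr1", "+", c(1000, 5500),
                           c(2300, 5800), gene_id = "q")
  expect_equal(
    classify_gene_difference(list(wide), ref, all_ref_genes = two_genes),
    "SPAN_MULTIPLE_LOCI"
  )

  # two non-overlapping query clusters inside one gene -> SPLIT
  left <- transcript_model("q.t5", "chr1", "+", 1000, 1210, gene_id = "q")
  right <- transcript_model("q.t6", "chr1", "+", 2000, 2300, gene_id = "q")
  expect_equal(classify_gene_difference(list(left, right), ref), "SPLIT")

  # exact copy -> IDENTICAL
  same <- transcript_model("q.t7", "chr1", "+", c(1000, 1500, 2000),
                           c(1200, 1700, 2300), gene_id = "q",
                           cds = c(1050, 2250))
  expect_equal(classify_gene_difference(list(same), ref), "IDENTICAL")

  expect_error(classify_gene_difference(
    list(transcript_model("far", "chr1", "+", 7e5, 7e5 + 100)), ref),
    "NOVEL_LOCUS")
})

test_that("collapse merges identical chains and widens terminal ends", {
  a <- transcript_model("r1", "chr1", "+", c(100, 300), c(200, 400))
  b <- transcript_model("r2", "chr1", "+", c(130, 300), c(200, 430))
  cc <- collapse_transcripts(list(a, b))
  expect_length(cc$isoforms, 1)
  expect_equal(transcript_span(cc$isoforms[[1]]), c(100, 430))

  # a 5 bp junction shift keeps the isoforms apart
  c2 <- transcript_model("r3", "chr1", "+", c(100, 305), c(200, 400))
  cc2 <- collapse_transcripts(list(a, c2))
  expect_length(cc2$isoforms, 2)

  # FL flag propagates from any member
  cc3 <- collapse_transcripts(list(a, b), is_fl = c(FALSE, TRUE))
  expect_true(cc3$is_fl[[1]])

  # every input maps to exactly one isoform
  expect_equal(sort(cc$members$input_id), c("r1", "r2"))
  expect_equal(length(unique(cc$members$isoform_id)), 1)
})

test_that("collapse recovers the planted isoform set from redundant reads", {
  g <- generate_genome(2, 80000, seed = 81)
  gm <- generate_gene_models(g, 12, seed = 82)
  set.seed(83)
  reads <- list()
  for (i in 1:200) {
    m <- gm$models[[sample(12, 1)]]
    st <- m$exon_start; en <- m$exon_end
    st[1] <- st[1] + sample(0:30, 1)
    en[length(en)] <- en[length(en)] - sample(0:30, 1)
    reads[[i]] <- transcript_model(sprintf("read%03d", i), m$contig,
                                   m$strand, st, en, gene_id = m$gene_id)
  }
  cc <- collapse_transcripts(reads)
  expect_length(cc$isoforms, 12)
  expect_equal(nrow(cc$members), 200)
  # idempotence
  cc2 <- collapse_transcripts(cc$isoforms)
  expect_length(cc2$isoforms, 12)
})

test_that("single-exon models merge by reciprocal overlap", {
  a <- transcript_model("s1", "chr1", "+", 100, 400)
  b <- transcript_model("s2", "chr1", "+", 250, 500)   # ~50% reciprocal
  c3 <- transcript_model("s3", "chr1", "+", 2000, 2300)
  cc <- collapse_transcripts(list(a, b, c3), single_exon_overlap = 0.4)
  expect_length(cc$isoforms, 2)
  # below the threshold they stay apart
  cc2 <- collapse_transcripts(list(a, b, c3), single_exon_overlap = 0.9)
  expect_length(cc2$isoforms, 3)
})

test_that("short-transcript removal uses the spliced length, strictly", {
  m99 <- transcript_model("m99", "chr1", "+", 1, 99)
  m100 <- transcript_model("m100", "chr1", "+", 1, 100)
  spliced <- transcript_model("sp", "chr1", "+", c(1, 200), c(49, 250))
  kept <- remove_short_transcripts(list(m99, m100, spliced))
  expect_equal(vapply(kept, function(m) m$id, ""),
               c("m100", "sp"))
  expect_length(remove_short_transcripts(list()), 0)
})
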