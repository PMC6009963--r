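test_that("intron-chain matching ignores terminal ends", {
  a <- transcript_model("a", "c", "+", c(100, 300), c(200, 400))
  b <- transcript_model("b", "c", "+", c(120, 300), c(200, 380))
  expect_true(intron_chain_match(a, b))

  extra <- transcript_model("e", "c", "+", c(100, 300, 500),
                            c(200, 400, 600))
  expect_false(intron_chain_match(a, extra))

  # fuzzed pairs equal a brute-force tuple comparison
  set.seed(14)
  for (i in 1:40) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    mk <- function(n, off) {
      st <- off + cumsum(c(0, rep(200, n - 1)))
      transcript_model(paste0("t", off), "c", "+", st, st + 100)
    }
    x <- mk(n1, sample(c(0, 0, 50), 1)); y <- mk(n2, sample(c(0, 0, 50), 1))
    brute <- identical(
      paste(transcript_introns(x)$start, transcript_introns(x)$end),
      paste(transcript_introns(y)$start, transcript_introns(y)$end)
    )
    expect_equal(intron_chain_match(x, y), brute)
  }
})

test_that("expression filter applies inclusive FPKM and replicate rules", {
  rec <- function(id, tissue, fpkms, matched = TRUE) {
    data.frame(transcript_id = id, tissue = tissue,
               replicate = seq_along(fpkms), fpkm = fpkms,
               intron_chain_matched = matched)
  }
  records <- rbind(
    rec("t1", "leaf", c(0.01, 0.01)),        # both replicates at boundary
    rec("t2", "leaf", c(0.009, 5.0)),        # one passing replicate
    rec("t3", "leaf", c(2, 3), matched = FALSE),
    rec("t1", "root", c(0.5, 0.02, 0.001))
  )
  ex <- expression_filter(records)
  key <- paste(ex$transcript_id, ex$tissue)
  expect_setequal(key, c("t1 leaf", "t1 root"))

  # brute-force recount on a random table
  set.seed(15)
  rnd <- expand.grid(transcript_id = paste0("x", 1:20),
                     tissue = c("A", "B"), replicate = 1:3,
                     stringsAsFactors = FALSE)
  rnd$fpkm <- round(runif(nrow(rnd), 0, 0.03), 4)
  rnd$intron_chain_matched <- runif(nrow(rnd)) > 0.2
  ex2 <- expression_filter(rnd)
  brute <- with(rnd, tapply(intron_chain_matched & fpkm >= 0.01,
                            paste(transcript_id, tissue), sum))
  expect_setequal(paste(ex2$transcript_id, ex2$tissue),
                  names(brute)[brute >= 2])

  # monotone: raising thresholds never adds transcripts
  ex_hi <- expression_filter(rnd, min_fpkm = 0.02)
  expect_true(all(paste(ex_hi$transcript_id, ex_hi$tissue) %in%
                    paste(ex2$transcript_id, ex2$tissue)))
  ex_rep <- expression_filter(rnd, min_replicates = 3)
  expect_true(all(paste(ex_rep$transcript_id, ex_rep$tissue) %in%
                    paste(ex2$transcript_id, ex2$tissue)))
})

test_that("tissue summary separates shared and tissue-specific sets", {
  ex <- data.frame(
    transcript_id = c("a", "a", "a", "b", "c", "c"),
    tissue = c("T1", "T2", "T3", "T1", "T2", "T3"),
    n_pass = 2
  )
  ts <- tissue_summary(ex)
  expect_equal(ts$shared_by_all, "a")
  expect_equal(ts$tissue_specific$T1, "b")
  expect_length(unlist(ts$tissue_specific[c("T2", "T3")]), 0)
  # shared set is inside every per-tissue set; specific sets disjoint
  sets <- split(ex$transcript_id, ex$tissue)
  for (s in sets) expect_true(all(ts$shared_by_all %in% s))
  sp <- unlist(ts$tissue_specific)
  expect_equal(anyDuplicated(sp), 0)
})

test_that("longest ORF matches the exhaustive codon walk", {
  expect_equal(longest_orf("ATGTAA"), 6)
  expect_equal(longest_orf("CCCCCCCCCC"), 0)
  expect_equal(longest_orf(""), 0)
  # ATG with no in-frame stop is not an ORF
  expect_equal(longest_orf("ATGAAAAAA"), 0)
  # frame-shifted ORF
  expect_equal(longest_orf(paste0("G", "ATGAAATAG")), 9)

  set.seed(16)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
    expect_equal(longest_orf(s), oracle_longest_orf(s))
  }
})

test_that("lncRNA cascade applies ORF, hit and score rules with stated boundaries", {
  seqs <- c(
    long_orf = paste0(strrep("C", 10), "ATG", strrep("AAA", 116), "TAA"),
    ok1 = paste0(strrep("C", 200), "ATGAAATAG", strrep("C", 200)),
    ok2 = paste0(strrep("G", 150), "ATGAAATAG", strrep("T", 150)),
    ok3 = paste0(strrep("G", 150), "ATGAAATAG", strrep("A", 2), strrep("G", 100))
  )
  expect_equal(longest_orf(seqs[["long_orf"]]), 354)  # excluded: > 350
  scores <- c(ok1 = -1.2, ok2 = -1.0, ok3 = -0.5)
  res <- lnc_cascade(seqs, coding_hits = "ok3", cp_scores = scores)
  expect_false(res$candidate[res$transcript_id == "long_orf"])
  expect_equal(res$call[res$transcript_id == "ok1"], "strong")
  expect_equal(res$call[res$transcript_id == "ok2"], "weak")  # -1 exactly
  expect_equal(res$call[res$transcript_id == "ok3"], "none")  # coding hit
  expect_true(res$coding_hit[res$transcript_id == "ok3"])

  # missing score for a surviving candidate is an input error
  expect_error(lnc_cascade(seqs["ok1"], cp_scores = numeric(0)),
               "missing coding-potential score")

  # cascade stages commute: filtering order cannot change the strong set
  res_b <- lnc_cascade(seqs[c("ok3", "ok2", "ok1", "long_orf")],
                       coding_hits = "ok3", cp_scores = scores)
  expect_setequal(res$transcript_id[res$call == "strong"],
                  res_b$transcript_id[res_b$call == "strong"])
})

test_that("lncRNA genomic context is assigned from annotation overlap", {
  ann <- list(transcript_model("r.t1", "chr1", "+", c(1000, 2000),
                               c(1500, 2500), gene_id = "r"))
  ctx <- function(model) isoforge:::lnc_context(model, ann)
  expect_equal(ctx(transcript_model("i", "chr1", "+", 5000, 5400)),
               "intergenic")
  expect_equal(ctx(transcript_model("n", "chr1", "+", 1600, 1900)),
               "intronic")
  expect_equal(ctx(transcript_model("s", "chr1", "+", 1200, 1400)),
               "sense")
  expect_equal(ctx(transcript_model("a", "chr1", "-", 1200, 1400)),
               "antisense")
})

test_that("homology filter honours e-value, bit-score fraction and reciprocity", {
  hits <- data.frame(
    query =   c("q1", "q1", "q2", "s1", "s2", "q3"),
    subject = c("s1", "s2", "s2", "q1", "q2", "s3"),
    evalue =  c(1e-12, 1e-11, 1e-8, 1e-12, 1e-9, 1e-30),
    bitscore = c(500, 450, 300, 480, 310, 700)
  )
  # GO-transfer thresholds without reciprocity
  kept <- homology_threshold_filter(hits, 1e-10, 0.90)
  expect_setequal(paste(kept$query, kept$subject),
                  c("q1 s1", "q1 s2", "s1 q1", "q3 s3"))
  # q1 s2: 450 >= 0.9 * 500 kept; e 1e-11 < 1e-10 kept; q2 dropped on e-value

  # reciprocal best-hit mode keeps only mutual best pairs: q1<->s1 in both
  # directions, plus q3/s3 whose single hit is trivially mutual; q1->s2 is
  # dropped because s2's best query is q2, not q1
  bbh <- homology_threshold_filter(hits, 1e-10, 0.90, bidirectional = TRUE)
  expect_setequal(paste(bbh$query, bbh$subject),
                  c("q1 s1", "s1 q1", "q3 s3"))

  # toy 6-row reciprocal table at the conservative screen thresholds
  kept_cw <- homology_threshold_filter(hits, 1e-20, 0.93)
  expect_equal(paste(kept_cw$query, kept_cw$subject), "q3 s3")

  expect_error(homology_threshold_filter(data.frame(query = "q")),
               "malformed")
  bad <- hits; bad$evalue[2] <- NA
  expect_error(homology_threshold_filter(bad), "row 2")
})
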