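---
title: "Methods: long-read transcript triage, mis-mapping statistics and splicing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read transcript triage, mis-mapping statistics and splicing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforge)
```

## Scope and data model

Single-molecule long-read sequencing of full-length cDNA yields reads long
enough to span entire transcripts, which makes it possible to observe
splicing isoforms directly instead of assembling them from short
fragments. The price is a high raw per-base error rate, which complicates
three steps that are trivial with accurate reads: deciding whether a read
is a complete (full-length, FL) cDNA, deciding whether its genomic
alignment is credible, and deciding whether a split alignment reflects a
real chimeric transcript or noise. isoforge implements these decisions,
the comparison of the resulting transcript models against a reference
annotation, alternative-splicing (AS) event calling with short-read
support rules, and the downstream expression and lncRNA filter cascades —
together with a synthetic-data generator that plants known isoforms,
events, fusions and error rates so every stage can be checked against
ground truth.

The universal currency is the `transcript_model`: a strand-aware chain of
exons on one contig. All coordinates in the package are 1-based and
closed, the convention shared by GTF and the R/Bioconductor interval
stack; GTF export therefore needs no coordinate shift. Derived quantities
(introns, junctions, spliced length) are computed on demand, and the
intron chain — the ordered list of intron coordinates — is the identity
of a spliced isoform throughout: two transcripts with identical chains
are the same structure regardless of their terminal ends.

## The mis-mapping statistic

Libraries of different insert sizes show stable median mismatch rates in
the 0.0072–0.055 range. Treating sequencing errors as independent
per-base events with a library-specific probability $p$, the number of
errors $K$ in an alignment of $L$ bases is $\mathrm{Bin}(L, p)$, and the
upper-tail probability of observing at least $K$ errors is approximated
by the de Moivre–Laplace normal limit

$$\Pr(X \ge K) \approx 1 - \Phi\!\left(\frac{K - Lp}{\sqrt{Lp(1-p)}}\right).$$

A small tail probability means the read has accumulated implausibly many
mismatches for its library and is most likely aligned to a homologous,
wrong locus. `mismap_pvalue()` implements exactly this quantity;
`mismap_flag()` implements the practical decision rule that flags an
alignment when $K > L(p + 0.03)$ — at this margin the corresponding tail
probability is vanishingly small for realistic $L$, so flagged reads are
confidently mis-aligned.

Numerical notes, all deliberate:

* The variance term carries the square root. Without it the expression is
  not a z-score and does not define a probability; the package treats the
  square-root form as the intended statistic.
* No continuity correction is applied by default; it is exposed as
  `continuity = TRUE`. The approximation error of the plain Gaussian tail
  is $O(1/\sqrt{Lp(1-p)})$ *near the distribution mode*: at $L = 2000,
  p = 0.02$ the maximal absolute deviation from the exact binomial
  survival function is below 0.02, but at $Lp \lesssim 10$ it reaches
  0.05–0.12. Decisions taken in the far tail (the only place the rule
  operates) are unaffected, but the p-value column should not be read as
  exact for short alignments; `stats::pbinom()` is the exact alternative
  when needed.
* `evaluate_fpr_fnr()` reports both orientations of "positive": with
  acceptance as the positive call, FPR is the fraction of wrong-locus
  alignments that escape the flag and FNR the fraction of correct
  alignments flagged; the transposed rates are returned alongside so
  either convention can be quoted.
* $p$ is taken per library (reads carry their library's error rate), not
  estimated per read.

Calibration is checked by simulation: 10,000 reads with
binomially-drawn error counts at $L = 2000$, $p = 0.02$ are flagged at a
rate within Monte-Carlo error of the analytic tail
$1 - \Phi(0.03\sqrt{L/(p(1-p))})$, and reads simulated at a mismatch rate
of $p + 0.06$ (a homologous locus) are flagged at a rate above 99%.

## Read triage

A read is FL when it carries the 5' primer near its start, the 3' primer
near its end, and a polyA run immediately upstream of the 3' primer;
the seven ways of missing these three signals define the non-FL classes.
Detection parameters, chosen to tolerate raw long-read error rates and
exposed as arguments:

* terminal search window 100 bp; primer matches allow edits up to 20% of
  the primer length (`Biostrings::matchPattern` with indels);
* polyA rule: a run of at least 20 bases with at most one non-A per ten,
  searched in the 60 bp upstream of the 3' primer (or the read tail when
  the primer itself was lost);
* both orientations are tried and the one with more signals wins.

The default primer family is a single-PCR-primer design: the 3' primer is
the reverse complement of the 5' primer's PCR core. This makes a read
carrying only the 5' primer indistinguishable, by signal *count*, from
the reverse complement of a read carrying only the 3' primer — the 5'
primer's shadow. Orientation ties are therefore broken by an
alignment-like score over the matched primers (matched length minus four
per edit): the genuine interpretation matches more primer sequence at
equal edits, while the shadow interpretation loses the template-switch
tail. With this rule the 8-way classification is exact on noiseless
synthetic reads and stays above 99% accurate at a per-base error rate of
0.02.

Artificial concatemers — two cDNAs ligated into one molecule — are
flagged when a primer occurs in the read interior, outside both terminal
windows, in either orientation. The strict length filter keeps reads
longer than 300 bp.

## High-quality alignments and fusion calls

Alignment identity is $(L - K)/L$ with $K$ counting mismatches and indel
bases uniformly; coverage is the aligned fraction of the read. The
high-quality filter keeps alignments with at least 90% identity and at
least 85% coverage (both inclusive), and `select_best_alignment()` keeps
the alignment maximising identity × coverage per read, breaking exact
ties by smallest (contig, start).

A split-mapped read becomes a fusion call when four criteria all hold:
(1) it maps to two or more distinct loci; (2) each locus carries at least
5% of the read; (3) combined coverage is at least 85%; (4) same-contig
loci are at least 100 kbp apart. Criterion (4) is implemented by
transitively merging same-contig segments closer than 100 kbp into one
locus before counting: a read split across 50 kbp is thereby a
single-locus read, not a fusion. Rejections record which criterion fired,
enabling a post-hoc audit that no accepted call violates any criterion.

Conventions on top of the criteria:

* "distinct loci" is defined purely by the distance rule; no annotation
  is required (an annotation-overlap filter can be applied downstream);
* redundant calls are grouped when their corresponding segment boundaries
  all agree within 50 bp (tolerance configurable); the longest read
  represents its group, ties broken by smallest transcript id, and the
  result is invariant to input order;
* calls are inter-chromosomal when their loci lie on different contigs
  (subtyped chromosome/scaffold by contig naming), intra-chromosomal
  otherwise;
* for matching against paired short reads, loci are keyed by (contig,
  10 kb bin of the segment midpoint); a call validates when every pair of
  its loci is linked by at least five read pairs.

## Transcript-versus-annotation classes

Each aligned transcript receives exactly one of nine codes describing its
relation to the annotation: structural match (identical intron chain),
novel isoform (shares at least one junction but differs elsewhere),
contained in a coding region, contains a whole gene, gene inside one of
the query's introns, intronic, partial exon overlap on the same or the
opposite strand, or novel locus (no overlap at all). When several could
apply, a fixed priority — strongest structural evidence first, in the
order given by `class_codes()` — makes the codes a partition; a fuzz test
over random layouts confirms exhaustiveness. Two conventions matter:
"contained in CDS" and "contains gene" require exonic contact, so a
transcript buried inside an intron is INTRONIC and a gene swallowed by a
query intron is GENE_IN_INTRON rather than being absorbed by the broader
span-containment codes; and single-exon structure matches use 50%
reciprocal overlap in place of the (empty) intron chain.

Matched genes are further compared at the gene level with precedence
SPAN_MULTIPLE_LOCI > SPLIT > GENE_STRUCTURE > SEQUENCE_SPAN > UTR_ONLY >
IDENTICAL: one query transcript covering several reference genes; several
disjoint query clusters inside one reference gene; different intron
chains; same chains but different spans with differing or absent CDS;
same chains and CDS with different ends; and exact agreement. The
precedence is a stated convention — each gene is counted once, strongest
difference first.

`collapse_transcripts()` reduces redundant reads to unique isoforms:
spliced reads merge on identical intron chains with terminal ends widened
to the outermost observed; single-exon reads merge transitively at 50%
reciprocal overlap; a merged isoform is FL iff any member was (the
FL-assembly rule). `remove_short_transcripts()` then drops models whose
spliced length is under 100 bp.

## AS events

Events are enumerated by pairwise structural comparison of a gene's
isoforms and deduplicated by (type, variable-region coordinates):

* **IR** — an exon of one isoform fully spans an intron of the other;
* **ES** — an internal exon lies entirely within an intron of the other;
* **A5SS / A3SS** — two introns share one boundary and differ at the
  other; donor/acceptor is resolved in transcription direction, so the
  genome-left boundary is the donor on `+` and the acceptor on `-`, and
  mirroring a gene to the opposite strand swaps the two types;
* **OTHER** — an isoform starts or ends inside an intron of the other
  (alternative terminal structure), reported only when the pair also
  shares a junction, which separates it from plain overlapping genes.

One disambiguation rule connects the types: when the differing region of
a shared-boundary intron pair swallows a complete exon of either isoform,
the pair is left to the ES/IR rules instead of producing a spurious
alternative-site call. The caller is checked against an independently
written brute-force enumerator on hundreds of random fixtures, and
planted events round-trip exactly — including their coordinates — on
noiseless data.

Validation rules: a junction is supported when at least five short reads
cover it in at least one sample (a mean-over-samples variant is also
reported); an event is short-read validated when it has at least one
inclusion read, at least one exclusion read and at least ten reads in
total; IR and ES events can additionally be validated against reference
transcript models by strict containment (a reference exon covering the
retained intron, or a reference intron covering the skipped exon — the
rule is not applicable to other types). Junction canonicity (GT–AG,
optionally GC–AG) is reported as a column when a genome is supplied.

## Downstream filters

* **Expression**: a transcript is expressed in a tissue when its
  assembly matched the reference intron chain and reached FPKM ≥ 0.01
  (inclusive) in at least two replicates. Tissue summaries report
  per-tissue counts, the intersection over all tissues, and
  tissue-specific transcripts, defined as expressed in exactly one tissue
  (a stated convention).
* **lncRNA cascade**: candidates have a longest forward-frame
  ATG-to-stop ORF of at most 350 nt (inclusive; the ORF length includes
  the stop codon). The candidacy rule is deliberately read as an
  ORF-length bound rather than a transcript-length bound — short ORFs,
  not short transcripts, are the signature of non-coding RNA. Candidates
  with a protein homology hit are removed; survivors are graded by a
  pluggable coding-potential score: strong below −1 (strict), weak in
  [−1, 0). The weak band is this package's convention and is recorded
  with the output. Each survivor is placed in genomic context
  (sense/antisense exonic overlap, intronic, intergenic).
* **Homology threshold filter**: hits must beat a strict e-value cutoff
  and reach a fraction of the query's best bit-score (inclusive);
  reciprocal-best mode additionally requires the pair to be mutual best
  hits. Typical settings are (1e-20, 0.93) for conservative screens and
  (1e-10, 0.90) for annotation transfer.

## The synthetic-data generator

The generator emulates the study conditions the analysis is designed for,
and its defaults are fixed rather than tuned:

* genomes are i.i.d. base draws at GC 0.46 (a typical grass value) over
  one or more contigs of at least 1 kb;
* gene models are non-overlapping, on both strands, with 3–6 exons of
  80–300 bp and introns of 60–400 bp by default; canonical GT..AG
  dinucleotides are written into the genome at every intron boundary;
* planted AS isoforms differ from their gene by exactly one event, with
  events allocated to disjoint introns/exons (see
  `?plant_as_isoforms`) so multi-event genes round-trip exactly;
* long reads carry the decoration of their drawn signal class; the
  non-FL class mix defaults to the three dominant observed classes —
  missing everything, missing 3' + polyA, missing 5' — in ratio 47:21:22
  with the remaining mass spread over the four minor classes; truncation
  removes up to 30% of a signal-less end;
* errors are i.i.d. per base in the supported range [0, 0.2] with an
  indel:substitution mix of 2:1, the typical composition of raw
  single-molecule reads; the mix is configurable because the true
  composition at any given error rate is instrument-dependent;
* the polyA tail is 30 nt, comfortably above the 20 nt detection rule;
  reads are emitted on either strand with probability one half;
* chimeric reads concatenate two isoforms' transcripts into one
  FL-decorated read; concatemers join two fully decorated cDNAs;
* short-read junction support is deterministic — each junction's count
  is the summed depth of the isoforms containing it — so planted support
  levels are exact; locus-link tables give a chosen subset of fusion
  pairs five-plus supporting pairs.

What the generator does *not* emulate: realistic signal-level error
profiles (errors here are position-independent), quality values,
polymerase-pass structure, expression-dependent coverage biases,
paralogous gene families, and genomes with repeats. Consequently, the
green tests demonstrate the correctness of the decision rules and
bookkeeping under the stated model — not the field performance of primer
detection or fusion calling on real instruments, where error clustering
and genomic repeats are the dominant failure modes.

## Problem sizes and determinism

The test-suite and the acceptance script use desk-scale problem sizes
chosen to exercise every rule while keeping the whole suite around a
minute: toy genomes of 2–3 contigs (60–500 kb), 8–24 genes, a few hundred
triaged reads per error rate, 10,000 simulated error-count draws for the
calibration checks, 20 planted fusions with 200 ordinary reads and 10
near-miss decoys, and 500 random fixtures for each oracle-equivalence
property. All generators take explicit seeds and are bit-reproducible for
a fixed seed; `scripts/acceptance.R` derives every sub-seed from its
`--seed` argument.

## Known limitations

* The Gaussian tail degrades for small $Lp$ (see above); exact binomial
  p-values are available trivially via `stats::pbinom` where that
  matters.
* Spliced alignment itself is out of scope: alignments enter as SAM/BAM
  (`read_alignments_sam()`) or, for synthetic data, are derived from the
  generator's truth records by edit distance.
* The gene-difference precedence and the weak-lncRNA band are
  conventions; both are stated in the output metadata and above.
* Fusion locus matching by 10 kb midpoint bins can split support across
  bins for loci spanning a bin edge; the bin width is configurable and
  the synthetic link tables place links at segment midpoints, where the
  effect cannot occur.
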