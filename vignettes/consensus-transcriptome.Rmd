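---
title: "Building and vetting a consensus transcriptome from many single assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and vetting a consensus transcriptome from many single assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensustx)
```

## The problem

De novo transcriptome assemblies of non-model organisms are built one
sequencing sample at a time, and no single sample reconstructs every
transcript well: deeply sequenced tissues yield full-length contigs for the
genes they express while others yield fragments or nothing. Pooling the
per-sample assemblies recovers the union of well-reconstructed transcripts,
but creates massive redundancy of two very different kinds:

* **cultivar alleles** — the same transcript differing by a handful of
  SNPs across accessions, which *should* be merged into one reference
  sequence; and
* **true isoforms** — distinct genes of very high similarity (the
  secologanin synthase pair SLS1/SLS2 and the tabersonine 16-hydroxylase
  pair T16H1/T16H2 sit near 96–97% nucleotide identity), which *must not*
  be collapsed.

`consensustx` implements the merge–cluster–filter procedure that threads
this needle, together with the quality metrics used to choose its
parameters and to audit the result.

## The clustering model

Pooled contigs keep provenance through `source_tag|contig_id` identifiers.
Clustering is greedy and incremental, the convention of the standard
nucleotide clustering tools: contigs are sorted by length (descending,
ties by input order); each contig either joins the first existing cluster
whose representative it matches at identity $\ge c$, or founds a new
cluster. Identity of a pair is

$$\mathrm{id}(a,b) = \frac{\#\{\text{identically aligned bases}\}}{\min(|a|,|b|)}$$

under an optimal end-gap-free (overlap) alignment, maximised over strands.
Dividing by the *shorter* length means a fragment exactly contained in a
longer contig has identity 1 and is absorbed — partial reconstructions are
credited to the transcript they came from rather than inflating the
catalogue. Because of the length-descending scan, every representative is
at least as long as its members, so the retained sequence is the best
full-length candidate of its cluster. `N` bases never count as matches.

The default threshold is $c = 0.97$: permissive enough that alleles a few
SNPs apart co-cluster, strict enough that 96%-identity isoform pairs stay
apart. `cluster_threshold_scan()` reproduces the scan (cluster counts at
$c \in [0.90, 1.00]$) used to justify the choice.

A conservative shared-word prescreen skips hopeless alignments: two
sequences at identity $\ge c$ over the shorter length $L_s$ must share at
least $L_s - n + 1 - n\lceil(1-c)L_s\rceil$ words of length $n$ (each
non-matching base destroys at most $n$ word positions; default $n = 9$).
The filter can only skip pairs provably below threshold, so clustering
with and without it is identical — a property the test suite checks
against brute-force runs across thresholds.

Alignment kernels (end-gap-free identity with match counting, and local
Smith–Waterman scoring, both affine-gap) are exact dynamic programming in
C++; the test suite cross-checks scores against
`Biostrings::pairwiseAlignment()` as an independent oracle. We chose exact
DP over a seed-and-extend heuristic because, at the problem sizes this
package targets, exactness is affordable and removes a whole class of
corner cases; `best_local_hits()` still applies a BLAST-like seed-word
gate (≥ 1 shared 11-mer by default) so that unrelated contigs are reported
as non-hits rather than as tiny chance alignments.

## The two-of-three cluster filter

Each cluster is scored on three axes: representative length, number of
member contigs, and summed FPKM over all members and samples. The
defaults — length $\ge 500$ bp (inclusive), contigs $> 10$ (exclusive),
summed FPKM $> 50$ (exclusive) — follow the printed rule; the boundary
cases therefore resolve pass/fail/fail. A cluster is discarded only when
**at least two** criteria fail. The disjunctive rule is deliberate:
a conjunctive filter would silently delete short genes and weakly
expressed rare isoforms, which are exactly the sequences the procedure
exists to protect. `filter_threshold_scan()` reports how many clusters
fall below candidate thresholds, the visual-inspection aid used to place
them. With no abundance table the filter degrades, with a warning, to the
two remaining criteria.

"Cluster length" is taken to be the representative's length (the
definition is otherwise open); the representative is the sequence actually
retained, so it is the length a downstream user experiences. Summed FPKM
is computed over member contigs (not just the representative), consistent
with the contig-to-cluster expression attribution below.

## Reconstruction quality and isoform prediction

For a panel of reference genes, reconstruction quality in an assembly is
the self-normalised bitscore ratio

$$\mathrm{ratio} = \frac{\mathrm{bits}(\text{best local hit})}{\mathrm{bits}(\text{gene vs itself})},
\qquad \mathrm{bits}(S) = \frac{\lambda S - \ln K}{\ln 2}.$$

A verbatim copy scores exactly 1; an exact half-length fragment of a
kb-scale gene scores ≈ 0.5; no positive-scoring hit scores 0. Because the
ratio is self-normalised it is nearly insensitive to the Karlin–Altschul
constants, which are supplied from a small nominal lookup (default scheme
+1/−2/−5 open/−2 extend, $\lambda = 1.28$, $K = 0.46$); chasing bit-exact
parity with any particular aligner release is explicitly not a goal.
Counting the contigs whose individual ratio exceeds 0.8
(`isoform_hit_count()`) flags putative isoforms: a gene present together
with a 97%-identity partner yields two hits.

`hit_coverage_table()` implements the companion bookkeeping for external
tabular hit sets: after an e-value cutoff (default `1e-20`), the
cumulative number of targets whose best hit covers at least 100%, 90%, …,
10% of their length.

## Expression: contig → cluster → concordance

Fragment counts convert to FPKM as $10^9 f / (L\,N)$. Contig-level FPKM is
attributed to clusters by summing members through the contig-to-cluster
map — the transcript-to-gene-map idea at cluster granularity — which
conserves per-sample totals exactly over mapped contigs. Cluster
expression is normalised to a designated housekeeping cluster (the RPS9
role), and agreement with qPCR is the adjusted $r^2$ of the simple
regression of $\log_2$ FPKM on $\log_2$ copy number over matched
(gene, sample) pairs. Pairs with a zero on either side are excluded and
counted, since $\log 0$ is undefined and the measurements carry no
magnitude information; an additive floor (`log_floor`) is available when
retaining them matters more than purity of the fit.

## Digital read normalization

The optional pre-stage caps transcript over-representation before
assembly. It is a streaming, deterministic rule: reads are visited once in
input order; a read is kept iff the *median* count of its canonical
k-mers (k = 25) among previously kept reads is below `max_cov`; kept reads
then update the counter. An identical read repeated a thousand times keeps
exactly `max_cov` copies; all-distinct reads pass untouched; the output is
a subsequence of the input and the operation is idempotent. Pair-aware
mode admits or rejects a read pair on the mean of the two medians so mates
are never orphaned. The default cap is 30, with 50 (the other commonly
used setting) one argument away. We chose streaming admission over
two-pass filtering because it is order-stable and reproducible by
construction.

## What the synthetic generator emulates — and what it does not

All moving parts are exercised by `generate_gene_set()` /
`generate_assemblies()` / `generate_expression()` / `generate_reads()`,
which emulate the statistical structure the procedure assumes:

* isoform pairs created by substitution-only mutation to a target identity
  (default 0.96) — `round((1-t)L)` substitutions at distinct positions,
  so realized identity is exact to rounding;
* cultivar alleles drawn from a per-gene panel of segregating sites
  (density `allele_rate`/kb, each cultivar carrying the alternative base
  with probability ½). Modelling shared polymorphic sites, rather than
  mutating every assembly independently, keeps pairwise allele identity
  ≥ 0.99 at realistic rates and mirrors how cultivar SNPs actually
  segregate;
* fragmentation into 1–3 pieces of ≥ 100 nt (uniform breakpoints), the
  partial reconstructions of shallow samples;
* log-normal expression with a constant housekeeping gene, split over a
  gene's contigs proportionally to length.

Defaults (12 genes of 0.9–1.5 kb, 2 isoform pairs, 5 assemblies,
fragmentation 0.3, dropout 0.1, allele sites 2/kb, 6 samples, log-normal
$\mu = 3, \sigma = 1$) are desk-scale stand-ins for the published corpus
(19 paired-end assemblies, 42 expression samples, millions of contigs).
The generator deliberately omits sequencing error, indel polymorphism,
chimeric contigs and paired-end insert geometry. Green tests therefore
demonstrate the *logic* — allele collapsing vs isoform preservation,
filter bookkeeping, conservation and concordance — not performance on
error-laden real assemblies, where clustering thresholds interact with
error rates in ways only real data can probe.

Every generator takes one seed; a single pipeline seed fans out to
per-stage child seeds by fixed arithmetic, so whole runs are bit-identical
and any stage can be reproduced alone.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 42)
summary <- run_pipeline(cfg, "run42")
report("run42")
```

The run directory contains, per stage, plain FASTA/TSV/`.clstr`/FASTQ
files plus `summary.json` with cluster accounting (total, singletons, true
clusters), filter accounting (retained + discarded = total, an identity
the tests assert), the gene × assembly quality matrix with hits > 0.8, and
the concordance fit.

## Numerical choices and degenerate inputs

* Ties everywhere are deterministic: length ties break by input order;
  equal-score alignments resolve toward more matched bases; `first_match`
  assignment follows representative creation order (the external tool's
  default), with `best_match` available.
* The empty overlap (score 0) is always admissible, so identity is 0 for
  sequences with no positively scoring overlap, never negative.
* Empty FASTA files parse to empty contig tables; empty cluster sets write
  empty `.clstr` files; an empty assembly yields an empty hit list and
  reconstruction ratio 0.
* Zero-variance participation vectors make assembly correlations
  undefined; they are reported as `NA`, not forced to 0.
* Reference-cluster normalisation refuses (with the sample named) to
  divide by a zero housekeeping value rather than emitting infinities.

## Known limitations

Clustering is single-threaded and quadratic in the worst case; the word
prescreen, not parallelism, is the scaling device, and corpus-scale inputs
(10^6 contigs) are out of reach of this implementation. The e-value
machinery of full BLAST statistics is not reproduced — reconstruction
ratios use raw-score self-normalisation, and e-values appear only as a
prefilter on externally supplied hit tables. Protein-space (translated)
search is not implemented.
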