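---
title: "mirpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirpipe` implements a complete small-RNA sequencing analysis for
replicated two-condition plant experiments of the kind used to profile
miRNA responses to water stress in soybean primary root tips: read
collapsing and length filtering, hierarchical annotation, RPTM
quantification with family pooling and abundance tiers, novel miRNA
discovery from hairpin precursors with miRNA-star validation, an exact
negative-binomial test for differential expression, and mismatch-bounded
target prediction with hypergeometric term enrichment. This vignette
records the models, the tunable parameters and the design decisions, in
the order the pipeline runs them.

## The annotation waterfall

Each unique read (uppercase, U converted to T) is assigned to exactly one
category by screening reference tiers in a fixed order:

1. **structural ncRNA** (rRNA, tRNA, snRNA, snoRNA) — exact substring
   match, either strand;
2. **repeats / mRNA** (transposons and protein-coding sequence) — exact
   substring, either strand;
3. **known miRNA catalog** — the full-length read may align inside a
   catalog entry with up to `mirbase_max_mismatch` substitutions
   (default 2, no indels; 0 gives exact-match mode), sense strand;
4. **genome** — exact substring, either strand;
5. **unmapped** otherwise.

Reads shorter than 18 nt or longer than 28 nt are removed before the
waterfall; both boundaries are inclusive on the retained side (an 18-mer
and a 28-mer are kept, a 17-mer and a 29-mer are not). The tier order is
the only precedence rule: a read matching both a tRNA and a catalog
mature is `noncoding`. A read keeps *all* catalog identifiers it matches,
because family pooling needs them, but its category is decided by the
tier alone. The published tally tables this reproduces list overlapping
categories whose rows sum to more than the library total; `mirpipe`
instead reports a disjoint partition (categories sum exactly to the
total) plus a separate "genome-mappable at any tier" figure, because the
partition is the quantity that can be asserted and tested.

The matching engine is `Biostrings::PDict` per read width for the
exact-substring tiers and a vectorized Hamming comparison against all
catalog windows for the mismatch-tolerant tier. Any engine producing the
same assignments is conformant; the tests only constrain assignments.

## Quantification

Abundances are normalized to **reads per ten million**:
\(\mathrm{RPTM} = 10^7 \, c / N\) for raw count \(c\) and library
denominator \(N\). The denominator is the total count of length-filtered
reads by default (`denominator = "filtered"`), which makes
\(\sum \mathrm{RPTM} = 10^7\) per library an exact invariant; the
genome-mappable total is available via `denominator = "genome"`. The
source study does not state its denominator, so the reproducible choice
is the default.

Family identifiers collapse member names by the `MIR<number>` convention
(`gma-miR156b-5p` → `MIR156`); identifiers already of that form are kept,
with trailing qualifiers removed, and unparseable identifiers pass
through flagged. Family counts pool each read once per family, however
many members it matched, so identical paralog matures are not double
counted. Star-strand reads (catalog ids ending `*`) are excluded from
family totals by default and summarized separately as star/mature RPTM
ratios.

Families are placed into four abundance tiers from their mean RPTM over
the control libraries, with lower-closed boundaries: high (≥ 100,000),
moderate ([10,000, 100,000)), low ([1,000, 10,000)), extremely low
([0, 1,000)). Only the lower closure of the high tier is stated by the
classification this mirrors; the remaining boundaries follow by symmetry.

## Novel miRNA discovery

Candidate reads are the genome-category reads pooled over libraries with
at least `min_count` reads (default 5 — the repetitive-read and
low-abundance cutoffs are not stated in the original analysis, so both
are exposed). Each read is mapped exactly to the genome on both strands;
reads with more than `max_loci` (default 5) hits are discarded as
repeat-derived. Around each locus a precursor window of ±150 nt
(`flank`) is extracted, reverse-complemented for minus-strand loci.

**Folding.** `fold_back()` is a maximum-weight nested base-pairing
dynamic program (Watson–Crick weight 1, G:U weight `gu_weight`,
minimum loop 3 nt) with a deterministic traceback that breaks ties by
pairing the 5'-most position first. It is exact: its pair counts equal
exhaustive enumeration over all nested structures, which the tests check
on random sequences up to 18 nt.

**Duplex location.** Pair-count maximization over a ~320-nt window is
massively degenerate: many structures achieve the optimal count, and the
traceback routinely assigns the mature arm's partners to random flank
positions, destroying genuine duplexes. Candidate evaluation therefore
uses `hairpin_structure()`: the star arm is located first by an ungapped
antiparallel complementarity scan of the mature against the window
(ties broken toward the nearest region, then the smallest coordinate),
those duplex pairs are fixed, and the remaining intervals are folded with
the same dynamic program, leaving unpaired mature positions unpaired.
The scan counts only Watson–Crick pairs by default (`duplex_gu = FALSE`):
treating G:U as pairing lets an unstructured 320-nt window reach the
mismatch threshold by chance with probability on the order of 2% per
window (the maximum over ~280 offsets of a Binomial(21, 0.375) tail),
whereas the strict reading keeps that probability near 10⁻⁵. Bulged
(indel-containing) duplexes are not modeled; the scan is
substitution-only.

**Duplex criteria.** A candidate passes when the mature lies on one arm
(not across the loop), has at most `max_mismatch = 4` unpaired positions
and no asymmetric bulge longer than `max_bulge = 2` nt. These defaults
follow the community hairpin-annotation guidelines, whose numeric values
are configurable because the original analysis cites the guidelines
without restating them.

**Star validation.** The expected star region is the segment pairing the
mature minus its 3'-terminal `overhang = 2` nt, extended by 2 nt at the
star's own 3' end — the canonical Dicer signature. A sequenced read is
star evidence when it occurs in the precursor with both ends within
`tol = 2` nt of that region; the most abundant such read is reported. A
novel miRNA is called only when the duplex passes *and* star evidence
exists; overlapping windows on one chromosome merge into a single call
keeping the most abundant mature.

## Differential expression

The log2 fold change is computed from pooled RPTM:
\(\log_2\!\big(\sum \mathrm{RPTM}_{\text{stress}} / \sum
\mathrm{RPTM}_{\text{control}}\big)\), with a pseudocount of 0.5 added to
both sums only when either is zero. This arithmetic reproduces the
published per-family fold-change values to within ±0.05 log2 units and is
therefore the default, rather than a shrunken model-based estimate.

Significance uses an exact negative-binomial test in the small-sample
tradition of count-based differential expression: a single common
dispersion \(\phi\) (variance \(\mu + \phi\mu^2\)) is estimated by
maximizing the within-condition conditional likelihood after scaling all
libraries to their geometric-mean size by total-count ratio; the
estimator returns 0 for under-dispersed data. Conditional on the pooled
total of a feature, the split between conditions is negative-binomial
(binomial in the \(\phi \to 0\) limit, which the tests check against the
closed form), and the two-sided p-value sums the probabilities of all
splits at most as likely as the observed one. P-values approximate, and
are not claimed to duplicate, those of the established exact-test
implementations; the tests verify rank agreement and call concordance
against one of them on simulated data. Benjamini–Hochberg FDR control and
the calling rule — stringent: |log2FC| ≥ 1 and FDR < 0.05; relaxed:
|log2FC| ≥ 1 alone — complete the module. A mean-abundance column
(log2 counts-per-million) is reported as a derived quantity only.

## Target prediction and enrichment

The reverse complement of each 18–28-nt miRNA slides along each sense
transcript; at each offset, positions score 0 (Watson–Crick), the
wobble weight (G:U, default 0.5, configurable to 0 or 1) or 1
(mismatch). Sites with score ≤ `max_mismatch = 3` — "fewer than 4
mismatches" — are kept, best site per transcript first. The scan is
substitution-only (no bulges), which keeps an exact per-offset
brute-force oracle. Term enrichment of target sets is the one-sided
hypergeometric over-representation test on user-supplied flat
annotations (no ontology propagation), BH-corrected across terms.

## The synthetic-data generator

The generator defines the study conditions for every test. A random
single-chromosome genome (default 50 kb) carries `n_hairpins` planted
precursors: a random mature arm (21 nt), a star arm built as its reverse
complement with `planted_mismatches = 2` substitutions chosen to pair
neither Watson–Crick nor G:U, a random 8–15-nt loop, and a 2-nt tail so
both duplex strands carry the 2-nt 3' overhang. Every planted mature
occurs exactly once in the genome and in no decoy; this is enforced and
tested. Libraries mirror the replicated design of the motivating study:
two conditions × `replicates_per_condition = 2`. Per-hairpin counts are
negative-binomial (`nb_dispersion = 0.1`) around means set by
`mirna_fraction = 0.35` of `library_depth`, scaled by
`2^condition_lfc[family]` in the stress condition; a `star_fraction`
(default 0.05, settable per family) of each family's reads is emitted as
the star strand. The remaining reads are background: 70% sampled from
the decoy features and 30% from uniform genome positions
(`background_decoy_fraction = 0.7`), with lengths drawn from a bimodal
plant-like distribution peaking at 21 and 24 nt. Background genome
positions overlapping a planted precursor are rejected and resampled, so
star-region evidence can only come from deliberately emitted star reads.
Each library contains exactly `library_depth` reads, which makes
depth conservation and RPTM conservation exact invariants.

What the generator does **not** emulate: sequencing error, adapter
contamination, quality-score structure, isomiR end heterogeneity,
strand-biased coverage, and bulged duplexes. Passing tests therefore
demonstrate correctness of the algorithms under clean planted truth, not
robustness to those artifacts in real libraries.

Problem sizes used by the test-suite and acceptance runs are deliberate:
libraries of 4–5 × 10⁴ reads, genomes of 40–60 kb, 8–10 hairpins,
500-feature calibration simulations, 200-sequence folding-oracle and
100-trial scanner-oracle checks. These sizes give stable statistics
(binomial standard errors well inside the asserted bands) while keeping
a full run in minutes.

## Numerical and degenerate-input conventions

* Tier boundaries are closed at the lower edge; `classify_tier` rejects
  negative input.
* `log_fold_change` is `NA` (flagged, not an error) when both pooled
  sums are zero.
* The exact test returns p = 1 for an all-zero feature; equalized
  pseudo-counts are rounded to keep an integer support.
* The dispersion search runs on log scale over [10⁻⁶, 10] and snaps to 0
  when the optimum is not better than the Poisson limit.
* All orderings (candidate merging, site lists, enrichment rows) carry
  explicit deterministic tie-breaks, and identical inputs yield
  byte-identical TSV outputs, which the acceptance checks assert.

## Known limitations

* The annotation waterfall is exact-substring outside the catalog tier;
  there is no spliced or indel-tolerant alignment.
* Free-energy folding is intentionally out of scope; a thermodynamic
  folder can be substituted behind the `fold_back` contract.
* Family collapsing is purely lexical (`MIR<number>`); unusual published
  family names can be handled by renaming the catalog.
* Enrichment treats annotations as flat sets; no ontology graph
  propagation is applied.
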