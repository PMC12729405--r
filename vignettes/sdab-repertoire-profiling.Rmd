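---
title: "Curating and profiling camelid sdAb repertoires"
author: "sdAbProfiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and profiling camelid sdAb repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdAbProfiler)
```

## Scope and model

A camelid VHH domain is seven consecutive segments,
FR1–CDR1–FR2–CDR2–FR3–CDR3–FR4: four framework regions forming the
conserved β-sandwich scaffold (stabilized by a disulfide between
canonical cysteines in FR1 and FR3) interleaved with three hypervariable
antigen-binding loops. The package treats a repertoire as a table of such
records and asks region-level questions: how conserved is each framework
position, how long and how variable is each loop per species, and where
do the chemically addressable residues (lysine, cysteine) sit.

The curation model is a funnel. Records enter from heterogeneous sources,
and each eligibility step removes a counted, attributed subset: species
harmonization (four accepted categories; generic labels such as "camelid"
or a bare "Camel" — which cannot distinguish Bactrian from dromedary
origin — become `AMBIGUOUS` and are excluded), mandatory-field
enforcement (identifier, species, and a full sequence or all seven
regions), sequence reconstruction, canonical-alphabet QC, exact
deduplication on the full-length sequence, and artificial-sequence
removal. The funnel invariant — records out equals records in minus the
sum of removals, with one verdict per removed record — is enforced by the
`SdAbSet` class validity and checked in the tests.

## Conservation and entropy

Regions are compared column-wise after right-padding each cohort's region
strings with `"-"` to the longest member. We deliberately do **not** run
a multiple sequence alignment: gap-opening heuristics in hypervariable
loops manufacture alignment artifacts that masquerade as conservation
signal. Padding keeps every deposited residue at its N-terminal-anchored
offset; the cost is that C-terminal loop residues of short members are
compared against padding (excluded from counts) rather than "aligned".

For column $j$, counts $n_{a,j}$ exclude gaps, $N_j=\sum_a n_{a,j}$,
consensus is the arg-max count with an alphabetical tie-break (the
tie-break is arbitrary but must be deterministic), consensus frequency is
$\max_a n_{a,j}/N_j$, and Shannon entropy is
$H_j=-\sum_a p_{a,j}\log_2 p_{a,j}$ in bits, bounded by
$\log_2 20\approx 4.32$. Columns with $N_j=0$ (all padding) are reported
as missing, not as zero — a zero would mean "perfectly diverse/conserved"
depending on the statistic and poison region means. Per-region summaries
average columns with $N_j\ge 1$, optionally coverage-weighted.

## Composition, lengths, and the test battery

Amino-acid frequencies are pooled: $f(a)=\sum_i n_{a,i}/\sum_i L_i$.
Pooling weights long sequences proportionally to their residue count,
which is the right denominator for "what fraction of residues in this
region are lysine"; the per-sequence mean is a different statistic and is
deliberately not used. For the conjugation-relevant residues the package
emits three complementary metrics per cohort and region — relative
frequency, mean count per sequence, and presence (fraction of sequences
with at least one) — because the three answer different engineering
questions and are easy to conflate.

Lengths are summarized with the sample (n−1) SD and RSD = 100·SD/mean.
Molecular weight uses average residue masses plus one water, reported in
kDa (a 124-residue VHH ≈ 13.5–13.6 kDa).

Group comparisons are non-parametric throughout: region lengths are
integer-valued, skewed and heavy-tailed, and Shapiro–Wilk rejects
normality for realistic cohorts. The battery is Shapiro–Wilk per group
(reported, not used as a gate), Kruskal–Wallis omnibus, and all pairwise
two-sided Mann–Whitney tests with Holm adjustment (normal approximation
with continuity correction — exact p-values are unavailable with ties,
which integer lengths guarantee). Cohorts below `min_n` (default 50) are
excluded from testing but always reported: a 35-record single-source
cohort cannot support distributional claims, and silently dropping it
would misrepresent the census.

## Boundary annotation

The reference path for FR/CDR delineation is externally supplied
numbering (e.g. an IMGT/ANARCI run), ingested as 1-based inclusive
boundaries and applied verbatim (`scheme = "imgt-external"`). The
built-in fallback (`scheme = "anchor-heuristic"`, flagged
`fallback_annotation`) is a deterministic motif-anchored splitter that
exploits the invariant residues of the Ig fold:

1. FR1 ends 3 residues after the first Cys in positions 16–35 (the
   canonical FR1 cysteine);
2. FR2 starts at the first Trp within 20 residues of the FR1/CDR1
   junction and has fixed length 17;
3. FR4 starts at the C-terminal-most `W-G-x-G` match;
4. FR3 ends 3 residues after its canonical cysteine, found by scanning
   **forward** for the first Cys compatible with the near-fixed FR3
   length (38), and FR3's start is placed 38 residues back.

Point 4 is a deliberate design choice: anchoring the FR3/CDR3 junction on
the *last* cysteine before FR4 would be simpler, but non-canonical
cysteines are *common* in CDR3 (present in the large majority of camel-
derived records) and would hijack a last-Cys anchor. Scanning forward
from a lower bound derived from the fixed FR3 length is robust to extra
cysteines in CDR1, FR2 and CDR3. All windows, offsets, fixed lengths and
the FR4 motif are configurable (`annotationConfig()`). The heuristic is
not a numbering scheme — it assigns no position numbers, handles no
insertion codes, and is only as good as its anchors; records whose
anchors are absent are dropped and funnel-logged rather than guessed at.

When a record carries both deposited regions and a disagreeing deposited
sequence, the regions win and the sequence is reset to their
concatenation (flag `sequence_region_mismatch`): all downstream analyses
are region-keyed. Records with partial regions and no full sequence are
removed at the mandatory-field step — reconstruction is strict
seven-part concatenation, so they could never be completed anyway.

## QC thresholds

Alphabetical-order detection requires non-decreasing residue order over
the whole string *and* at least 5 distinct residues, so it never fires on
homopolymers — each removal is attributed to exactly one rule. The
low-complexity rule fires on a single-residue run of 10+ or a dominant
residue strictly above 50% of the sequence. No public threshold exists
for "extended runs"; these defaults are conservative (real VHHs rarely
exceed runs of five) and configurable. A 50/50 two-residue repeat
deliberately does not fire. Ambiguity codes (X/B/Z) reject a record at
QC; gap-masking of stray non-canonical characters applies only inside
the alignment module, where a masked residue becomes missing data rather
than grounds for exclusion.

## The synthetic generator

`generateRepertoire()` emulates the features the pipeline must detect:
four species with distinct CDR1/CDR2/CDR3 length laws, near-fixed
framework lengths (25/17/38/11) with conserved consensus strings and low
substitution noise, FR3-concentrated lysines with a secondary FR2
contribution, canonical FR1/FR3 cysteines, species-dependent
non-canonical cysteine placement (random position in CDR1/CDR3, a fixed
conserved position in FR2), plus injected exact duplicates and
alphabetical/homopolymer decoys — all recorded in a truth manifest.

Parameter defaults are the published per-species cohort summaries:
CDR length means/SDs such as alpaca CDR3 15.2 ± 4.4 aa and llama CDR1
8.8 ± 2.1 aa; non-canonical cysteine probabilities 0.8 for Bactrian and
dromedary CDR1/CDR3, 0.1 for llama CDRs, 0.4 for the alpaca FR2 position;
default cohort sizes mirror the reference census (325/35/377/1316).
CDR lengths follow a normal law rounded to integers with a floor of 3 —
the simplest law matching the two published moments; its exact mean and
SD (the rounding adds 1/12 to the variance) are what parameter-recovery
tests compare against. Invariant anchor residues (canonical cysteines,
FR2 Trp, FR4 motif) are never substituted, mirroring their biological
invariance; CDR composition excludes Trp and Cys by default so that loop
anchors stay unambiguous and every extra cysteine is an explicit,
manifest-recorded event. One seed (default 20251125) drives all
randomness through a single stream; identical configurations produce
byte-identical outputs.

What the generator does *not* emulate: germline V-gene usage, somatic
hypermutation structure, position-specific loop composition, length-
dependent loop chemistry, or realistic metadata sparsity. Passing
recovery tests therefore demonstrates that the *pipeline's estimators
are unbiased at realistic parameter values and sample sizes* — not that
real repertoires obey these laws.

## Problem sizes and numerical choices

The test suite exercises parameter recovery at 1,000 records per species
(recovery gates at 3 standard errors of the generating law), annotation
round trips on 1,000 generated records, oracle equivalence of the
entropy/consensus implementation against a brute-force tally on 1,000
random small columns at 10⁻¹² tolerance, and the test battery's
operating characteristics over 200 replicate null pairs (type-I error
within 3 binomial SE of 5%) plus a +1-residue shift detection at
n = 300/group. Entropy uses base-2 logarithms on counts > 0 only;
0·log 0 terms are dropped, never evaluated. Ties in consensus counts,
duplicate survivors (source priority, then lexicographic identifier) and
filter order are all fixed deterministically so reruns are
byte-identical.

## Limitations

- Deposited region boundaries from different sources may follow different
  numbering dialects; the `scheme` tag preserves this provenance rather
  than resolving it, and cross-source position-level comparisons inherit
  that heterogeneity.
- The fallback annotator assumes the camelid scaffold (fixed FR2/FR3
  lengths, intact anchors); heavily engineered or truncated constructs
  should come with external boundaries.
- Exact-duplicate removal only: near-duplicates (one substitution apart)
  are retained by design, and clustering is out of scope.
- The statistical battery compares location shifts; it makes no claims
  about variance differences beyond what RSD tables describe.
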