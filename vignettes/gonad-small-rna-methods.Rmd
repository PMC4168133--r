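---
title: "Methods: the gonad small RNA annotation cascade and its statistics"
author: "gonomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gonad small RNA annotation cascade and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonomiR)
```

## The analysis problem

Teleost gonads express two dominant small RNA populations: Dicer products
(miRNAs, with a length mode at 22–23 nt) and PIWI-interacting RNAs (piRNAs,
26–31 nt, germline-enriched). Comparing pooled libraries from XX ovary, XY
testis and YY super-male testis asks three questions: which species are
detected where (presence/absence set accounting), which co-detected species
differ in abundance between libraries (count-based differential expression
without biological replicates), and which reads belong to which RNA class in
the first place (annotation). gonomiR implements this workflow end to end
and ships a ground-truth simulator so every stage can be tested against a
known answer.

## Preprocessing

Reads are machine-length (36 nt by default) with the 3' adapter filling the
space beyond the insert. `trim_adapter()` scans every placement of the
adapter prefix (minimum overlap 6 nt) allowing at most one substitution and
cuts at the leftmost acceptable placement; indels are not modeled because
small RNA 3' adapters dominate read ends and ligation chemistry rarely
introduces gaps at the junction. `filter_reads()` then keeps reads of
16–30 nt (both bounds inclusive — the conventional reading of a
"between 16 and 30 nt" rule), with no ambiguous base and mean Phred
quality of at least 20. Neither the junk-read definition nor a quality
cutoff is standardized in this kind of study; both are explicit, documented
parameters here. Every dropped read is charged to exactly one reason
(length, then N content, then quality), so the filter statistics partition
the input and read-count conservation can be asserted at every stage.

Clean reads are collapsed to unique tags (`collapse_tags()`), the atoms that
flow through the rest of the pipeline, with one count column per library.
The length histogram (`length_profile()`) is computed over distinct
sequences by default — the convention used to assess library quality — and
peak windows are maximal runs of lengths whose counts exceed 1.5 times the
median bin count.

## The annotation cascade

`classify_cascade()` assigns every tag exactly one category, in a fixed
priority order; the order of the removal classes (mRNA, rRNA, tRNA, snRNA,
snoRNA, repeat) is a convention, fixed and configurable, because known-RNA
removal is order-insensitive for disjoint reference sets. Removal matching
is exact by default (tolerance configurable); miRNA and piRNA matching
allows one substitution, the conventional homology tolerance for ~22-mers.

Conserved miRNAs are tags matching a mature reference with at most one
mismatch. When the hit's precursor maps to the genome the tag is called
`conserved_miRNA_genome`; when it does not, the tag's own genomic context
must fold into a valid hairpin (`conserved_miRNA_hairpin`) — two evidence
tiers that mirror how real pipelines fall back from precursor-level to
locus-level support when the study species lacks its own genome. Tags with
no mature hit that map exactly to the genome are novel-miRNA candidates:
windows extending 70 nt on either side of the locus (a 15 nt pad on the
opposite side; both orientations tried) are folded, and a passing hairpin
yields `novel_miRNA`. Remaining tags are screened against the piRNA set and
finish as `piRNA_homolog` or `nohit`. Multi-mapping ties break
deterministically: fewest mismatches, then lexicographic reference id, then
offset. Curated single-stranded sets are matched on their forward strand;
the genome on both strands.

### Hairpin validation

`fold_hairpin()` accepts a candidate precursor (50–200 nt) when

* the structure is a single predominant stem-loop — exactly one hairpin
  loop after discarding helices shorter than three stacked pairs, so stray
  isolated pairs in the flanks cannot masquerade as extra stems;
* the mature sequence lies entirely in one arm (5p or 3p);
* at least 14 of its bases pair with the opposite arm; and
* the folding score passes: minimum free energy at most −18 kcal/mol for
  the thermodynamic backend, or a paired fraction of at least 0.55 for the
  built-in backend.

Two backends are provided. `"rnafold"` shells out to ViennaRNA's `RNAfold`
for a true MFE structure. `"nussinov"` is a built-in maximum base-pairing
dynamic program (Watson–Crick plus G:U wobble, minimum loop 3, deterministic
outermost-first traceback) that needs no external binary. `"auto"` prefers
RNAfold when it is on the PATH. The pass thresholds are this package's
concretization of "default folding criteria": −18 kcal/mol sits well below
the MFE of typical ~70–90 nt pre-miRNAs while rejecting unstructured
sequence, 14 duplex bases corresponds to a mature ~22-mer with a handful of
bulged positions, and a 0.55 paired fraction plays the analogous role for
the pairing-count backend, whose score is not an energy.

### piRNA homology

Tags are aligned ungapped against the piRNA set (at most one substitution)
and accepted when the Karlin–Altschul E-value

E = K · m · n · exp(−λS),  S = matches·s_match + mismatches·s_mismatch

falls below 1e−4, with m the tag length, n the total piRNA database length,
scores +1/−2, and λ the positive root of Σᵢⱼ pᵢpⱼ exp(λ sᵢⱼ) = 1 on uniform
base composition (λ ≈ 1.3347 for +1/−2). K, which Karlin–Altschul theory
only defines through a slowly converging series, is fixed at 0.1 — a
typical ungapped value; since E scales linearly in K, any choice in the
usual 0.05–0.35 range moves the decision boundary by less than one matched
base. The E-value filter is what makes short (16 nt) coincidental matches
against a large database fail while a full-length 26–31 nt match passes by
many orders of magnitude.

## Expression and differential calls

Counts are normalized to reads per million: NE = count / total × 10⁶.
The normalization total defaults to the summed miRNA counts of the library
(so NE columns sum to 10⁶ exactly); a clean-read total is available as a
configuration switch, since either denominator is defensible and published
tables have used both.

For a pair of libraries A and B, `call_de()` applies, in order:

1. **Low-abundance filter.** Species with NE below 1 in *all three*
   libraries are `filtered` — removed from testing and from the
   multiple-testing family.
2. **Sex-specific rule.** Species with zero NE in exactly one member of the
   pair are `specific_A`/`specific_B` and are not tested; a presence/absence
   contrast carries no meaningful fold change.
3. **Testing.** Remaining species get three p-values for the 2×2 contrast
   of counts against library totals: the Audic–Claverie conditional test,
   Fisher's exact test (two-sided by the point-probability rule) and the
   1-df chi-squared test (continuity correction off by default). The
   driving p-value is Audic–Claverie by default (`policy = "ac"`);
   `"consensus"` uses the maximum of the three, i.e. all tests must agree.
4. **Correction and calling.** The driving p-value is Bonferroni-multiplied
   by the number of species actually tested in this pair and capped at 1.
   `up` requires adjusted p < 0.05 and log2(NE_A/NE_B) > 1; `down` the
   mirror image.

Because zeros are routed to the specific rule before testing, tested rows
always have positive NE in both libraries and no pseudocount is needed. The
0.01 replacement for zero NE exists only in `plot_values()`, for log-scale
scatter plots, and never touches the matrix.

The Audic–Claverie two-sided p-value is min(1, 2·min(P(k ≤ y | x),
P(k ≥ y | x))) under p(k | x) ∝ (N2/N1)^k (x+k)! / (x! k! (1+N2/N1)^(x+k+1)),
evaluated in log space; the upper tail is summed directly rather than via
1 − lower, which would cancel catastrophically when the tail is small.
Two numerical facts are worth knowing and are covered by tests: the
doubled-minimal-tail construction is only approximately symmetric under
exchanging the two libraries (the conditional pmf obeys an exact exchange
identity with a factor N1/N2, and at equal library sizes the two
orientations differ by at most the boundary point mass, a factor of two);
and the chi-squared approximation departs from the two exact tests by
orders of magnitude in deep tails, so "the three tests agree" is an
asymptotic statement about moderate significance at counts of a hundred or
more.

Abundance tiers follow copy-number boundaries: High above the dataset mean
copy, Middle above 10 and at most the mean, Low at most 10 reads; boundary
cases are assigned downward because the published wording is strict on both
sides and silent on equality. The per-species copy number within a pair is
the mean of its two counts.

`ddct()` implements 2^(−ΔΔCt) relative quantification for the qPCR
validation arm (reference gene 5.8S rRNA in the motivating design): the
control condition maps to 1 by construction. `welch_t()` wraps the
two-sided Welch t-test for triplicate comparisons.

## Set accounting

Detection means NE > 0 — published three-library Venn counts are
presence/absence based, and a minimum-count variant is available as an
option. `venn_partition()` computes the seven disjoint regions and derives
per-set totals, pairwise co-detection counts (pair-only region + triple),
union size and percentages of the union to one decimal.

`solve_partition()` goes the other way: given only the three per-set
totals, the three exclusive counts and a single pair-only region — the
numbers such studies print — the remaining two pair-only regions and the
triple overlap are determined by the per-set identities, a 3-unknown linear
system solved exactly, with infeasibility (negative or non-integer regions)
reported by name. Solving from a realized partition's marginals reproduces
the partition exactly whenever the system is determined, a round-trip the
test suite asserts on random partitions.

Hierarchical clustering for heatmap row ordering uses log10(NE) with zeros
revised to 0.01 (the same convention as the scatter plots), Euclidean
distance and complete linkage — the metric and linkage are conventions,
fixed and configurable — with rows sorted by id beforehand so the leaf
order does not depend on input order.

## The simulator: what it emulates, and what it does not

`generate_reference()` builds a self-consistent toy reference: mature
miRNAs (22–23 nt, mode 22) embedded in near-palindromic stem-loop
precursors (arm + ≥6 nt loop + reverse-complement arm with up to three
engineered mismatches on the arm opposite the mature), placed without
overlap on a toy genome; rRNA/tRNA/snRNA/snoRNA, mRNA and repeat references
with a small canonical fragment set per reference (real degradation
fragments are stereotyped, which keeps distinct-sequence diversity
realistic); and a piRNA set with lengths peaked at 26–28 nt. Precursors
pass hairpin validation by construction, so annotation ground truth is
well-defined.

`simulate_library()` draws read counts multinomially from a category
mixture (defaults: miRNA 0.35, piRNA 0.20, known RNA classes 0.37,
unassignable 0.08), with per-miRNA log-normal base abundances, optional
gamma overdispersion, engineered fold changes (a +2 spec multiplies the
species' weight by 4 in the target group), group-exclusive species, a
per-base substitution error rate (default 0.008) and a junk fraction
(default 0.02: random insert, uniformly low quality, so the quality filter
has real work). Reads are written at fixed machine length with the adapter
filling the 3' end. Each library gets its own RNG stream keyed by (seed,
group), so a fixed seed reproduces FASTQ bytes exactly and adding a library
does not perturb the others.

Default sizes — 150 miRNA species, 800 piRNA species, depth 1e5 — are set
so that the distinct-sequence length histogram reproduces the bimodal
Dicer/piRNA profile of real gonad libraries: the 22–23 nt peak is carried
by abundance-weighted substitution variants of a few hundred species, the
26–28 nt peak by piRNA species diversity. The test suite's end-to-end
experiment uses 50 miRNA species at depth 1e5 per library with ten
engineered two-fold-log2 changes, three group-exclusive species and zero
error rate, sizes at which the suite runs in well under a minute per stage
on a single core.

The simulator deliberately does **not** model ligation bias, PCR
duplication, RNA modifications, isomiR length heterogeneity,
inter-individual variance (the motivating design pools individuals into
one library per group, so there are no replicates to emulate), or genuine
transcriptome complexity. Passing tests therefore demonstrate that the
pipeline's logic is correct on data satisfying its assumptions — they say
nothing about, for example, adapter chemistry artifacts or the adequacy of
Bonferroni correction on thousands of real species.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  reports.
* `audic_claverie_p` is evaluated in log space with `lgamma`; tails are
  summed to machine convergence. Agreement with direct summation is tested
  to 1e−10 relative over 500 random instances.
* `fisher.test`/`chisq.test` from base R stats provide the exact and
  asymptotic 2×2 tests; a degenerate all-zero-margin table yields p = 1.
* Empty inputs error early with informative messages (empty length
  profile, fewer than two clustering rows, zero normalization totals,
  infeasible Venn marginals named by region).
* Ties everywhere break lexicographically (reference ids, tag sequences,
  clustering row ids), making every output deterministic under a fixed
  seed.

## Known limitations

* The removal steps are exact-match by default; a mismatch-tolerant removal
  (as some pipelines use) is available but changes the conserved/novel
  split downstream.
* The built-in folder maximizes pairing, not energy; its paired-fraction
  threshold is a proxy and the two backends can disagree near the decision
  boundary. The thermodynamic backend is preferred when available.
* With one library per group there is no replicate-aware dispersion
  estimate; the three count-based tests share the equal-rate null and
  their p-values understate biological variability, exactly as in the
  motivating design.
* The Venn detection rule (NE > 0) counts single-read species; a
  minimum-count threshold changes exclusive counts first.
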