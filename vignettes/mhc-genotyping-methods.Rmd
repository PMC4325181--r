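---
title: "Replicated-amplicon MHC genotyping: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicated-amplicon MHC genotyping: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

## The problem

Classical MHC loci are duplicated, highly similar, and amplified together by
degenerate primers, so a single PCR on one bird returns a mixture of alleles
from about six class I loci — between 4 and 12 distinct alleles per
individual. Amplicon sequencing of such mixtures is contaminated by three
artefact classes: substitution/indel errors from PCR and pyrosequencing,
PCR chimeras joining the 5' part of one template to the 3' part of another,
and one-off noise reads. Worse, alleles differ systematically in how well
they amplify; an allele with a relative efficiency of ~0.2 sits at read
frequencies *below* the artefact background, so naive read-count thresholds
silently drop it (allelic dropout), biasing homozygosity and diversity
estimates.

`mhctyper` implements the replicate-validated filtering strategy for this
setting: every sample is amplified and sequenced twice with different dual
10-bp barcodes (MIDs) in different pools, artefacts are identified by their
frequency behaviour within and between the two replicates, per-allele
amplification efficiencies are estimated from the read counts of called
genotypes, and a minimum read depth (a modified Galan T1 threshold) defines
when an amplicon is deep enough to genotype reliably. A companion set of
sequence-analysis tools computes the summary statistics used to
characterise the resulting allele sets: variable sites, minimum mutations,
nucleotide diversity, Watterson's theta, the Hudson-Kaplan four-gamete
recombination minimum, Nei-Gojobori/Jukes-Cantor dN/dS over
peptide-binding-region (PBR) partitions, and z-descriptor supertype
clustering.

## The classification cascade

Reads are quality-filtered (Phred > 20 at more than 95% of bases; both
comparisons strict, per the protocol wording — relax the thresholds if you
need non-strict behaviour), demultiplexed by exact dual-MID match with
IUPAC-aware primer verification, trimmed to template, and grouped into
clusters of identical sequences. Then:

1. **Within each amplicon.** The most frequent cluster is a putative allele
   (on ties, all tied clusters are; symmetric treatment avoids arbitrarily
   discarding a true allele). Single-read clusters are discarded. Every
   other cluster is labelled `chimera` if it can be assembled, at any
   breakpoint, from a prefix of one strictly more frequent cluster and a
   suffix of a *different* strictly more frequent cluster; otherwise it is
   labelled by its minimum Levenshtein distance to any strictly more
   frequent cluster (`1-2 bp` vs `>2 bp`). Edit distance (substitutions and
   indels) is used because indels are a dominant 454-style error mode; the
   chimera check takes precedence over the distance label.
2. **Between replicates.** `chimera`/`1-2 bp` clusters absent from the
   sample's replicate amplicon are artefacts, as are clusters chimeric in
   both replicates; `>2 bp` clusters unique to a single amplicon in the
   whole data set are artefacts. The rest are retained.
3. **Frequency test.** Retained clusters present in both replicates become
   putative alleles in an amplicon iff their intra-amplicon frequency
   exceeds every entry of that amplicon's artefact list (an empty list
   passes vacuously), and unclassified variants otherwise. Retained `>2 bp`
   clusters seen in only one replicate are unclassified if the sequence is
   a putative allele in another individual, artefacts if not; retained
   chimeras are alleles only when the same sequence is an independent
   putative allele in another individual. The comparison is
   amplicon-local because frequencies are amplicon-normalised; whether the
   original procedure compared within the amplicon or globally is not
   decidable from its description, so the local reading (the conservative
   one for low-frequency alleles) is the default.

**Post-processing, large data sets** (hundreds of individuals), in order:
(a) putative alleles confirmed in only one individual are dropped — they
cannot be distinguished from sample-specific artefacts; (b) unclassified
variants matching a surviving catalog allele are promoted in their samples;
(d) artefact entries matching a catalog allele, present in both of a
sample's amplicons at a frequency above the least frequent entry of the
data-set-wide putative-allele list, are promoted; (c) variants present in
both amplicons of more than 80% of individuals *while remaining
unclassified there* are added to the catalog as **low-efficiency alleles**.
The flag condition deliberately requires unclassified status, not mere
presence: a well-amplifying common allele is occasionally unclassified in
an unlucky amplicon, but only a poorly amplifying allele is consistently
present below the artefact background. Flagged alleles are reported in
every carrying sample together with the flag, so downstream users can
exclude them from presence/absence analyses while keeping them for
sequence-level statistics. Promotions never resurrect alleles dropped by
(a); the prevalence rule (c) can still add such a sequence, but only with
the low-efficiency flag attached.

**Post-processing, small data sets** (a handful of individuals): a variant
that is a putative allele in both replicates of even one sample is kept; a
variant called in a single amplicon but observed as an unclassified variant
in other samples is kept; unclassified variants present in both replicates
of at least two birds are promoted.

Repeatability is the percentage of alleles shared between a sample's two
replicate calls, with the union of the two call sets as denominator
(Jaccard x 100); a mean-size denominator is available behind the
`denominator` argument.

## The simulator and what it emulates

`study_design()` defaults reproduce the emulated study: 320 samples
screened twice (640 amplicons) in eight pools of 80; nine forward x nine
reverse Roche MIDs (81 combinations per pool, pairwise distance >= 3);
~240 bp templates between the degenerate DG2 and GENDG primers; six loci
with 4-12 alleles per individual; per-allele relative efficiencies; and a
negative-binomial read depth with mean 1,430 and dispersion 5 (matching the
reported mean +/- SD of roughly 1,430 +/- 650 and the long lower tail down
to ~45 reads), truncated at 30 reads. Replicates of a sample always sit in
different pools with different MID pairs. All randomness derives from named
substreams of one master seed, so pools, genotypes and reads are
independently reproducible and serialised runs are byte-identical.

The allele-pool generator builds variation the way exon-3 allele sets look:
divergence confined to a minority of "hotspot" sites, with derived states
shared between alleles (identical by descent). Defaults — 22 alleles,
240 bp, ~90 variable-capable sites, ~16 substitutions per allele from the
ancestral haplotype, a rare second derived state at 7% of substitution
events, and two alleles carrying one in-frame 3-nt insertion — were fixed
from the study's design point: they imply ~85-90 variable sites, a
minimum-mutation count ~15-25% above the variable-site count, mean pairwise
differences ~26-27 nt and nucleotide diversity ~0.11 for a 22-allele set,
the regime reported for this system. The generator is neutral with respect
to protein effects: it excludes in-frame stop codons but does not emulate
selection, so synthetic dN/dS ratios hover near 1 and should not be read as
biological signal.

The error model has two channels, and the distinction matters:

* **Late (per-read) errors** — substitutions at 5e-4/base, 1-2 bp indels at
  1e-2/read, one-off noise reads at 1e-2 — produce almost exclusively
  singleton clusters, which is what step 1's singleton discard is for.
* **Amplified artefact lineages** — a Poisson(4) number of 1-2 bp mutant
  lineages per amplicon at intra-amplicon frequencies U(0.005, 0.035), and
  chimeric reads (5% of the amplicon, parents drawn proportionally to read
  share, breakpoint uniform) concentrated into a Poisson(3) number of
  recurrent parent/breakpoint lineages. This channel models errors arising
  in *early* PCR cycles that are then amplified like templates; it is the
  reason real amplicons contain artefact clusters at frequencies of several
  percent — above the read share of a low-efficiency allele — and without
  it the step-3 frequency test would be vacuous and the allelic-dropout
  phenomenon unreproducible.

Simulated reads carry a two-state quality model (Phred 37 bases, with 2%
of bases at Phred 12), which gives the strict ">20 at >95%" filter a crisp
expected pass rate. The simulator does not model flowgram-level homopolymer
noise, emulsion-PCR duplicates, or base-caller pathologies beyond the four
artefact classes; passing the recovery tests therefore shows the filtering
logic is sound under realistic artefact loads, not that any particular real
run will reach the same accuracy.

## Amplification efficiency and the T1 threshold

The efficiency model assumes an allele's amplification efficiency is a
property of the allele, independent of genotype, and that each called
allele contributes one template copy. Within an amplicon, the expected log
read-count ratio of two co-amplified alleles is then the difference of
their log efficiencies. All within-amplicon pairs with both counts >= 1
enter a weighted least-squares fit (amplicons weighted by total reads; zero
counts contribute no pair, and no pseudo-counts are added), anchored by the
reference allele at efficiency 1. The reference is arbitrary — with
degenerate primers the best-amplifying allele is unknowable — so estimates
are relative, and multiplying all true efficiencies by a constant leaves
them unchanged. Alleles with no co-occurrence path to the reference are
reported as missing rather than guessed. The single-copy assumption is a
known bias: the simulator's locus model gives homozygous loci copy number
2, which perturbs counts by at most a factor of 2 on a scale where true
efficiencies span ~0.2-3.9; parameter-recovery tests use single-copy
genotypes to isolate the estimator's own error (Pearson r > 0.995, all
estimates within ~7% at 200 amplicons x 1,000 reads).

The minimum read depth is defined conservatively: for a worst-case genotype
of `k` alleles in which one allele amplifies at the lowest observed
efficiency `e_min` and the rest at 1, the weak allele's expected read share
is `p_min = e_min / (e_min + k - 1)`, and T1 is the smallest depth `N` such
that `Binomial(N, p_min)` yields at least `m_min = 2` reads with
probability 0.999. Each replicate must reach the threshold independently;
a sample with an under-sequenced replicate is excluded with a logged
reason. The original threshold function lives in another study's
supplementary scripts and its printed values (139; 291) are not
reproducible from published quantities, so this package defines T1 by the
binomial construction above and validates its monotonicity properties
instead of any specific printed number (at k = 12, e_min = 0.2 the
construction gives 513 reads — deliberately more conservative).

## Sequence statistics: conventions

* **Gap handling.** Alignment-wide statistics (S, eta, pi, k, theta, Rm)
  use complete deletion of gap-containing columns, the convention of the
  standard polymorphism software this mirrors; pairwise dN/dS skips gapped
  codon pairs (pairwise deletion), matching the distance software
  convention.
* **Theta.** Both variants are returned; `theta_w` is S-based
  (`S / sum(1/i)`), which is the variant consistent with the printed value
  we could verify for this system; `theta_w_eta` gives the eta-based
  alternative.
* **NG86.** Synonymous site fractions count only non-stop single-base
  changes (denominator excludes stops); multi-step codon differences are
  averaged over all minimal substitution pathways, excluding pathways
  through stop codons (with the unrestricted average as fallback if every
  pathway is blocked); proportions are Jukes-Cantor corrected, and pairs
  with p >= 3/4 are reported missing rather than extrapolated. An
  independently coded brute-force implementation in the test suite agrees
  to 1e-10.
* **Rm.** Four-gamete-violating site pairs are reduced to the minimum
  number of non-overlapping intervals by the greedy right-endpoint scan;
  tests verify it against an exhaustive minimum-cover search. Coalescent
  confidence intervals are out of scope.
* **Mann-Whitney tests** on pairwise distance matrices ignore the
  non-independence of pairs sharing a sequence, exactly as is customary
  for such summaries; treat the p-values as descriptive.
* **PBR positions are an input** (one 1-based codon index per line; see
  `inst/extdata/example_pbr_positions.txt`, an illustrative example file,
  not a published site map), because the defining study inherits them from
  prior structural homology work rather than printing them.

## Supertypes

Unique binding-site sequences are encoded as rows of the five Sandberg
z-descriptors per analysed position. The cluster number scan runs k-means
(k-means++ seeding, 100-iteration cap, best of 4 runs per k) for k from 1
to the number of rows and scores each k by
`BIC = n ln(WSS/n) + k ln(n)`, averaged over runs; the chosen k minimises
the mean BIC, with ties going to the smaller k. WSS is floored at machine
epsilon so the perfect fit at k = n stays finite; with all-distinct,
well-separated rows the minimum lands at k = n — every allele its own
supertype, the outcome reported for this system. The published procedure
used a PCA-based clustering front end whose truncation settings are
unstated; this package clusters the raw descriptor matrix, which is
exactly reproducible and gives the same all-singleton behaviour in the
regime that matters here. Positions where any sequence carries a gap (the
1-residue insertion) are dropped by default with a message; `strict = TRUE`
turns that into an error.

## Numerical and design details

* Cluster ordering: count descending, ties broken lexicographically by
  sequence, so reports are deterministic.
* "Presence in the replicate" means presence among the replicate's
  non-discarded (count >= 2) clusters; singletons are treated as
  sequencing noise everywhere after step 1.
* Sequence matching in all promotion rules is exact string equality of
  trimmed templates; no mismatch tolerance.
* MID matching is exact (the chosen MIDs differ by >= 3 bases; 1-mismatch
  rescue would be safe but is not what the emulated protocol did); primer
  matching is IUPAC-aware and positional, with no fuzzy alignment. Reads
  are single-orientation, forward key end first.
* All trimming uses 0-based half-open indices internally; serialised
  reports are 1-based.
* Test and acceptance problem sizes: the pipeline recovery check runs
  310 samples x 2 replicates x ~1,430 reads over 5 seeds (~890k reads per
  seed); dropout uses 60 twelve-allele samples; estimator recovery uses
  200 amplicons x 1,000 reads; the chimera detector is compared with brute
  force on 10^4 randomized instances (<= 6 clusters, length <= 50); Rm and
  NG86 are checked against exhaustive oracles on 100 mosaic alignments and
  20 random codon-sequence pairs. These sizes were chosen to match the
  emulated study's scale while keeping a full run in a few minutes.

## Limitations

The deposited allele sequences of the motivating study are not bundled, so
the sequence-statistics acceptance run operates on the package's synthetic
allele set; its diversity statistics sit at the study's design point by
construction, but dN/dS and supertype outputs on synthetic data reflect the
neutral generator, not selection at a real MHC. The pipeline assumes exact
replicate structure (two amplicons per sample); samples missing a replicate
are flagged and skipped rather than single-replicate-genotyped. Loci are
not phased: calls are allele presence/absence per individual, not per-locus
genotypes.
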