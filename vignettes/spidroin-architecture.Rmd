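---
title: "Dissecting repetitive spidroin genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting repetitive spidroin genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidrhom)
```

`spidrhom` analyzes genes with the canonical spidroin layout — a long
array of near-identical tandem repeat units between short, non-repetitive
N- and C-terminal coding regions — and the clone-survey data used to count
gene copies in individual genomes. This vignette is the package's account
of the underlying models: what is computed, which knobs matter, which
conventions were chosen where the science leaves the choice open, and what
the synthetic-data generator does and does not emulate.

## The architecture model

An ORF is modeled as `n_term | R1 .. Rn | c_term`, where every repeat unit
except possibly the last has one fixed length (the *period*, a multiple of
3 so units respect the reading frame), the final unit may be a truncated
prefix of the others, and the terminals are unrelated to the unit
sequence. The ORF convention includes the stop codon in the reported
length: a 13,440 nt ORF encodes 4,479 residues plus the stop, which keeps
nucleotide and protein bookkeeping consistent (13,440 / 3 − 1 = 4,479).
Coordinates are 0-based half-open everywhere in the programmatic API and
1-based inclusive only in serialized reports.

### Period detection

`detect_period()` scores every codon-multiple shift `p` in
`[min_period, max_period]` by the mean per-base identity between the ORF
and itself shifted by `p`, over the overlap. For a tandem array every
multiple of the fundamental period scores almost as high as the period
itself, so the reported period is the *smallest* shift within `tol`
(default 0.01) of the maximum. A configurable floor (default 0.60)
declares sequences without tandem structure rather than returning a
meaningless argmax. Defaults `min_period = 90`, `max_period = 2100`
bracket known spidroin unit sizes (tens to hundreds of codons).

### Segmentation

`segment_repeats()` scans all codon-aligned phases in `[0, period)`
exhaustively — the delimitation procedure is this package's own
definition, since published spidroin annotations report results, not
algorithms. For each phase the ORF is tiled into full-length windows, a
majority consensus of the windows is built, and windows at least
`terminal_threshold` (default 0.5) identical to the consensus count as
repeats. The unmatched flanks are then re-fit: full units are recovered
one period at a time, and at most one truncated unit per side is accepted
by a maximum-scoring overlap `matches − 0.72·k` against the consensus
prefix (3′) or suffix (5′). Three numerical choices deserve explanation:

* **The 0.72 slope** approximates the log-likelihood-ratio changepoint
  between near-identical repeat sequence (~98% per-base identity) and
  unrelated terminal sequence (~25% chance identity): a codon matching
  2/3 by chance must not extend the repeat array, while a genuinely
  repeat-derived codon carrying one substitution should.
* **Snap-to-full-period**: when a full unit fits and scores within 1.0 of
  the overlap maximum, the overlap snaps to the full period, so a single
  mutated boundary codon does not shave a codon off a full unit.
* **Minimum truncated overlap (15 nt)**: a couple of chance-matching
  codons are not a truncated repeat; accepting them both misplaces a
  boundary and, through the truncation penalty, distorts the phase
  competition.

Phases compete on total repeat-region matches, with truncated overlaps
entering net of the slope and of a fixed per-truncation cost
(0.25 × period). The cost resolves a real degeneracy: a tandem array
truncated at one end admits two mirror tilings — truncated unit first or
truncated unit last — with identical total match counts. The package
follows the spidroin-annotation convention that truncation sits at the 3′
end, implemented as a higher cost (×1.4) for 5′ truncations. A final unit
kept as a repeat rather than fused into the C-terminal is exactly the
published situation of a truncated last repeat.

`decompose_gene()` chains ORF finding, period detection, segmentation and
region extraction; `write_gene_model()` serializes the result.

## Homogenization statistics

Percent identity is `100 × identical columns / counted columns`. Columns
gapped in both rows are never counted; a one-sided gap is skipped under
the default *pairwise deletion* policy and counted as a mismatch under
`gap_mismatch`. Published repeat-identity figures rarely state their
denominator, so both policies are exposed and the truncated final repeat
can simply be dropped from the input rows when an ungapped comparison is
wanted; at ≥98% identity the policies differ by well under a percentage
point. `N` counts as a mismatch.

The internal aligner is a center-star progressive global aligner over an
exact Gotoh pairwise core (match 1, mismatch −1, gap −2 by default; affine
when `gap_ext ≠ gap_open`). For coding sequences, `mode = "codon"`
translates, aligns in protein space and back-threads gaps as whole
codons — the protein alignment dictates the nucleotide alignment. A
progressive aligner is a deliberate simplification: the sequences this
package aligns (repeat units, amplicon clones, consensus repeats) are
near-identical, where any sensible global aligner returns the same
answer; the pairwise core is checked exhaustively against a brute-force
dynamic-programming oracle in the test suite.

Majority-rule consensus treats the gap as a residue, drops gap-majority
columns from the consensus string, and breaks ties toward the
alphabetically first residue — determinism over hidden state — flagging
every tie in an attribute. Positional profiles report, per alignment
column, the fraction of non-reference rows matching the reference row;
`region_means()` averages the profile inside user-supplied 0-based
half-open domain annotations (e.g. structural helix assignments).

## Variant diagnosis

The unit of analysis is a clone set: all amplicon clones from one
individual and one region. The pipeline is mask → discard → cluster →
count, in that order (an option flips mask/discard for sensitivity
analysis):

1. **Singleton masking.** A residue carried by exactly one clone in a
   column whose majority residue is carried by at least two is attributed
   to polymerase error and replaced by the majority; residues shared by
   two or more clones are never touched. In a 2-clone set every
   difference is a reciprocal singleton and the rule is self-contradictory,
   so masking is skipped with a warning rather than guessing.
2. **Unsupported-pattern discard.** A clone survives only if its residue
   pattern across all polymorphic columns is identical to another
   clone's; chimeric patterns (recombinants of two templates' alleles)
   are unique and fall out here.
3. **Clustering.** Single-linkage agglomeration on percent identical
   sites, cutting so that members join at > 95% identity (the threshold
   is the only quantitative rule the source procedure states; the
   original clustering was visual, on neighbor-joining trees, which the
   trees module still draws for inspection). Clusters of one clone emit
   no variant; each surviving cluster's majority-rule consensus becomes a
   variant call supported by ≥ 2 clones.
4. **Minimum copy number.** A diploid carries at most two alleles per
   locus, so `n` variants imply at least `⌈n/2⌉` loci (`ploidy` is a
   parameter; 2 is the default for spiders, which are not known to be
   polyploid).

The whole chain is scored against simulation truth in the tests: over the
parameter box 2–5 loci, 4–10% template divergence, 4–10 clones per
template and error rates 10⁻⁴–10⁻³, called variants match the true
templates with precision and recall ≥ 0.95 and the minimum-locus bound
never exceeds the true count. Template recovery is only well-posed when
templates are mutually separable at the clustering threshold, so the
generator used in those tests enforces pairwise identity < 95%.

## Selection

`pairwise_dnds()` implements Nei–Gojobori counting: per-codon synonymous
site fractions enumerate all single-base changes, excluding changes to
stop codons from the denominator (so each codon still carries 3 sites);
multi-difference codon pairs average over all orderings of the differing
positions, excluding pathways through stop codons (if every pathway is
blocked, all pathways are counted with stop steps as nonsynonymous rather
than dropping the codon). Jukes–Cantor correction
`d = −3/4 · ln(1 − 4p/3)` is applied to both proportions; raw proportions
are always reported, and the correction is flagged undefined at
`p ≥ 3/4`. When dN is exactly 0 against real synonymous divergence the
ratio is reported as 0 even if the dS correction saturates.

`region_dnds()` averages over all sequence pairs and reports the **ratio
of means** as the headline number: the mean of pairwise ratios is biased
upward for diverged pairs (Jensen's inequality on a noisy denominator) and
undefined whenever any pair has dS = 0, both of which the ratio of means
avoids; the mean of ratios is reported alongside for transparency. Under
neutral simulation the ratio of means converges to 1, which the tests
verify. `classify_selection()` calls ratios within 0.05 of 1 neutral,
below purifying, above positive. A counting estimator was chosen over
codon substitution models deliberately: it is fully specified,
dependency-free and transparent; model-based estimates on the same data
will differ by several hundredths, which is why region-level comparisons
in this package are about ordering and regime, not third decimals.

## Trees

Neighbor joining, midpoint rooting, monophyly and newick I/O delegate to
`ape` and `phangorn` — standard, well-tested implementations — behind a
thin validation layer (symmetry, zero diagonal, ≥3 taxa; negative NJ
branch estimates clamped to 0 and flagged). Distances are p-distances
from the identity module. `bootstrap_support()` resamples alignment
columns with replacement under a caller-supplied seed and reports, for
each internal edge, the fraction of replicate NJ trees containing that
bipartition. Maximum-likelihood inference is out of scope: every grouping
claim this package makes (species-specific repeat clades, variant
grouping) is qualitative clade membership, for which NJ on p-distances
suffices.

## The synthetic-data generator

`simulate_gene()` grows a gene by tandem duplication of one random
ancestral unit between random terminals, with codon usage skewed toward
serine/alanine/glycine to mimic silk composition. Defaults mirror the
aciniform architecture: 612 nt units, 20 repeats, 510/330 nt terminal
spans, diploid genomes, PCR error 5×10⁻⁴ per base per clone, 6 clones per
template. Two generator-level conventions keep the simulated truth
well-defined:

* Junction codons are redrawn so a terminal never ends (or begins) with
  the codon the adjacent repeat position carries — otherwise the true
  boundary is genuinely ambiguous and "boundary recovery" would be
  ill-posed.
* During `evolve_loci()`, mutations that would create an in-frame stop,
  destroy the start codon or destroy the terminal stop are rejected: an
  intact ORF is a survival condition for a functional gene copy. PCR
  errors in `simulate_clones()` carry no such constraint.

Evolution is generation-wise: per-base substitution at `mutation_rate`
(terminals at `terminal_rate_multiplier` times that — the published
pattern of divergent terminals and homogenized repeats), a
`synonymous_bias` knob that redirects the stated fraction of coding
mutations to synonymous alternatives (sites with none reject the
mutation), and Poisson-distributed gene conversion modeled as whole-unit
copy-paste between two random repeat units of the same gene copy.
Whole-unit conversion is the simplest mechanism producing the observed
signature — within-gene homogenization — and is not a tract-length model;
terminals never convert because they have no repeat partner. No
selection, recombination between loci, indels or coalescent demography is
simulated, so passing tests demonstrate that the estimators recover the
processes in this model, not that real data are free of the confounders
the model omits (PCR chimeras exist in the tests only as a fixed
constructed example). Mutation and conversion rates are illustrative —
chosen to reproduce the qualitative identity regimes of real spidroin
data (>98% within a gene, diverged terminals) — not inferred from data.

All randomness flows through R's RNG under explicit integer seeds; the
same seed reproduces every simulated object byte for byte.

## Problem sizes

The test suite and the acceptance script run at deliberately moderated
sizes chosen to exercise every code path while keeping a full run in the
minutes range: full-scale architecture recovery uses one 13,440 nt gene
per run; repeat-recovery properties use 20 replicates of 10–25 units of
600 nt at ≤2% per-copy mutation; variant-recovery properties use 50
seeded surveys of 300 nt amplicons; conversion monotonicity uses 30 seeds
of a 6-unit, 120 nt-unit gene over 100 generations; oracle equivalences
use 1,000 random pairs (aligner), 100 random additive trees (NJ) and all
pairs from a 20-codon panel (dN/dS).

## Known limitations

* The aligner is center-star progressive with affine gaps; for the
  near-identical sequences this package targets that is sufficient, but
  deeply diverged inputs (e.g. cross-genus terminal domains) would
  deserve a profile-based aligner.
* Segmentation assumes a single-period array; nested or higher-order
  repeat structure is not modeled.
* dN/dS is counting-based and pairwise; site-wise models and
  recombination-aware tests are out of scope, and region estimates on
  concertedly evolving repeats violate the independence assumptions of
  any dN/dS method — they are descriptive summaries, not tests.
* The minimum-locus bound is exactly that: a lower bound. Assigning
  variants to named loci or phasing alleles requires data this analysis
  does not use.
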