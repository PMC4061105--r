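---
title: "Dissecting profile-HMM alignment scores into segment contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting profile-HMM alignment scores into segment contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmdissect)
```

## Why dissect a similarity score

Sequence similarity is a necessary but insufficient condition for
homology. Profile-HMM searches report a single total log-odds score per
domain-to-sequence alignment, and that total can be carried past any
E-value threshold by segments that say nothing about a shared fold:
low-complexity stretches, long loops, coiled coils, transmembrane runs.
Conversely, a genuinely homologous core can be dragged below threshold
by heavy penalties accumulated over such remnant regions.

The remedy implemented here is postmortem score dissection. The total
score of an alignment is rebuilt term by term from the model parameters,
each term is assigned to a *fold-critical* (FOLD) or *remnant* (REMNANT)
segment of the domain model, and the two class sums are evaluated as
E-values independently. A hit is only credible as a homology statement
if its fold-critical contribution is significant on its own — or at
least more significant than the remnant contribution. No search
algorithm needs to be modified or re-run: the dissection consumes the
alignments and the model file that a search already produced.

## Score reconstruction

For an alignment path through the model, the total score in bits is

$$v = \sum_i \log_2 e(Y_i \mid X_i) + \sum_i \log_2 t(X_i \mid X_{i-1})
      + \log_2 t(X_0) + f,$$

the sum of per-step emission log-odds (match and insert states),
per-step transition log-odds (including the begin-to-match entry and
match-to-end exit), and a position-invariant fixed score $f$. All of
these are stored in HMMER2-format ASCII model files as integers in
1/1000-bit units, with `*` marking an impossible transition
(`parse_hmmer2_model()` maps it to `-Inf`). $f$ is assembled from the
`XT` line; for a single-domain alignment we take
$f = XT_{N \to B} + XT_{E \to C} + XT_{C \to T}$, omitting the
per-residue flank terms ($N \to N$, $C \to C$) and the multi-domain
$J$ loop, which do not depend on the alignment through the model.

Models produced by converting a local (HMMER3-style) parameterisation
to the HMMER2 format keep only the entry into state 1 and the exit out
of state $K$; the other local entries/exits appear as `*`. When a
fragment of a local alignment starts mid-model, the missing entry score
is *omitted* rather than treated as $-\infty$: the per-hit sum then
carries a small, documented approximation, which is why per-fragment
sums are reported as approximate while the per-hit sum is the supported
quantity. A `*` anywhere else (an emission, an internal transition)
propagates and makes the score $-\infty$, as it must.

### Term assignment

The original formulation never states which segment a transition score
belongs to, so the package fixes a total assignment rule that makes the
partition exact and testable:

* an emission at model position $k$ belongs to $k$'s class;
* a transition *into* position $k$ belongs to $k$'s class;
* the exit $M_K \to E$ belongs to $K$'s class;
* insert emissions and $I \to I$ self-transitions belong to the class of
  the last match/delete position visited (their anchor).

With this rule `fold_score + remnant_score + f == total_score` holds
bit-exactly for every path and every segmentation, and the test suite
asserts it as an invariant. The fixed score is counted in the total
E-value but in neither class sum: it is constant per model, and the two
undefined rows of the hit-label table (below) are exactly the patterns
only $f$ can produce.

## E-values

Significance uses the maximum-Gumbel survival scaled by the database
size:

$$E = N \left(1 - e^{-e^{-\lambda (v - \mu)}}\right).$$

$(\mu, \lambda)$ come from the model's `EVD` line; converted models
lack one and are flagged uncalibrated, in which case `evalue()` and
`dissect()` require explicit values rather than guessing defaults. The
implementation evaluates the outer $1 - e^{-x}$ via `expm1`, so for
strong scores it degrades gracefully into the asymptotic
$N e^{-\lambda(v-\mu)}$ instead of underflowing to zero; at the far
insignificant end $E$ saturates at $N$ once the survival equals 1 to
machine precision. The default $N$ is 540261 sequences
(UniProt/SwissProt, April 2013), overridable everywhere. Sub-scores
reuse the model's single $(\mu, \lambda)$; no per-segment recalibration
is attempted. The diagnostic ratio $E_1/E_2$ (fold-critical over
remnant) summarises a hit: $\ll 1$ supports homology, $\approx 1$ is
on-par, $\gg 1$ flags similarity carried by remnant segments.

## Segmentation schemes

**DSSP.** Positions whose aligned residue carries one of the
secondary-structure codes H, B, E, G, I, T, S are FOLD; the blank loop
code and the alignment gap are REMNANT. Delete-state positions receive
the gap marker and therefore count as unstructured — the source
material is silent on this case and the gap reading is the
conservative one.

**Alignment quality.** When no structure is available, per-column
conservation of the seed alignment is the surrogate. For column $j$
with residue counts $F_j$ and substitution matrix $C$ (BLOSUM62 from
Biostrings by default) the consensus vector is $X_j = F_j^T C / M$, and
each non-gap residue's distance to it is the Euclidean norm
$D_{ij} = \lVert X_j - C_{\cdot, a_{ij}} \rVert_2$. In the signed variant the distance is a plain sum of differences, which lets positive
and negative deviations cancel; the Euclidean form follows the CLUSTALX
source and is the default, with `distance = "signed"` available for
comparison. The raw quality $Q_j = \sum_i D_{ij} / M$ (divisor $M$,
total sequences, so sparse columns are already down-weighted) is
min-max inverted to $\hat Q_j \in [0, 1]$ and scaled by the non-gap
fraction, $\tilde Q_j = (k_j / M)\hat Q_j$. A perfectly homogeneous
alignment makes the min-max step degenerate; all $\hat Q_j$ are then
set to 1 (maximal consensus), a choice the original description leaves
open. Positions with $\tilde Q \ge$ cutoff are FOLD.

Cutoff defaults: 0.06 for SMART-like and 0.14 for Pfam-like seed
alignments, the operating points at a 5% false-positive rate in the
large-scale SMART/Pfam calibration against sparse columns, whose
arithmetic `calibrate_cutoff()` reproduces. Columns need at least
5 non-gap residues to carry any power at $\alpha = 0.05$: the exact
binomial tail at $p = 0.5$ is 0.0625 at best for $M = 4$
(`min_sequence_pvalue()`), so sparser columns are only eligible as the
negative calibration class.

**SEG-derived.** SEG itself is consumed, not re-implemented: the input
is a per-residue 0/1 mask (1 = high-complexity) projected from the
ungapped sequences onto alignment columns, as produced by SEG with
window 25 and cutoffs 2.9/3.2. Per column, the binomial tail of the
positive count is tested at $\alpha = 0.05$; on rejection
$k_{exp} = P(X \ge k)\,k$, otherwise $k_{exp} = 0$, and
$p_{exp} = 0.01$ if $k_{exp} = 0$, else $k_{exp}/M$; columns with
$p_{exp} \ge 0.8$ count as high-complexity (FOLD). Taken literally,
the product rule makes $p_{exp}$ *small* precisely when every sequence
is confidently high-complexity ($M = 8, k = 8$ gives
$p_{exp} \approx 0.004 < 0.8$), which looks inverted relative to the
stated intent. The literal formula is nevertheless the default, and
`complement = TRUE` switches to $k_{exp} = (1 - P(X \ge k))\,k$, which
behaves as the intent suggests. The package takes no position on which
variant the original software ran.

## Hit classification and engine comparison

With three E-values per hit (total, fold-critical/high-quality,
remnant/low-quality) and a significance call at 0.1, `label_hit()`
assigns TP (total and fold significant), TN (neither), FP (total
carried by the remnant part only) and FN (fold significant but total
dragged down); the two remaining patterns — expressible only through
the fixed score — are UNDEF and practically non-existent.

`pair_hits()` matches hits from two engines when they lie on the same
sequence with overlapping segments (one shared position by default; a
minimum overlap fraction is configurable). Many-to-many overlaps are
resolved greedily by decreasing overlap length with ties broken on the
smaller start coordinate, a deterministic rule chosen because the
source material only requires "a common sequence segment". Orphans are
excluded from every denominator. Pairs fall into positive concordance
(both engines call the hit true, labels in {TP, FN}), negative
concordance (both false), or the two discordance types;
`domain_rates()` reports these as percentages that sum to exactly 100,
plus the FN rate (pairs TPFN + FNTP + FNFN — obscured true homologies)
and the FP rate (pairs FPTN + TNFP + FPFP — score-inflated false
hits). A commonly stated form of the FP rate repeats the FN
numerator, an evident typo; the mirrored form used here is the only
reading consistent with the concordance table.

## Synthetic data: what it emulates and what it does not

The fixture module generates every input format with known ground
truth: models with 1/1000-bit integer scores (glocal-style entries by
default, `local_entry = TRUE` for local-style), alignment paths with an
independently hand-summed score, seed alignments with planted
conserved/noisy column blocks, DSSP-like label runs, SEG-like masks
and two-engine hit tables. The naive per-term score oracle lives in
this module, deliberately outside the production scoring path.

Study conditions used by the tests and the acceptance script, chosen
once as a realistic regime and not revisited: seed alignments of
$M = 8$ sequences with two 20-column blocks, consensus probability
0.95 in conserved columns, uniform residues in noisy columns, 5% gaps;
quality segmentation at cutoff 0.5, the midpoint of the min-max
normalised scale, since planted conserved and noisy columns
concentrate near the two ends of $[0,1]$ (the SMART/Pfam defaults 0.06
and 0.14 are operating points of the large-scale library calibration,
not of this synthetic design). Score-reconstruction checks use 100
random model/path pairs (model lengths 5–20, deletion and insertion
probabilities 0.15); quality-score equivalence uses 200 random
alignments with $M \le 8$, $N \le 12$; hypergeometric equivalence is
exhaustive for tables with $N \le 12$ and randomised up to margins of
60; recovery uses 50 seeds.

What passing these tests shows: the arithmetic of reconstruction,
partition, normalisation and rate computation is exact, and the
segmentation machinery recovers planted conservation structure under
realistic noise. What it does not show: real seed alignments have
phylogenetic correlation between rows, composition bias and indel
structure that the independent-column generator does not emulate, and
real engine-reported scores differ from the reconstruction by rounding
and by the converted-model approximations discussed above. Claims
about live HMMER searches therefore rest on the format fixtures
(genuine `hmmbuild`/`hmmconvert`/`hmmsearch` outputs on a toy
alignment) and on the reconstruction contract, not on the synthetic
statistics.

## Numerical choices and degenerate inputs

* Integer fields are bits × 1000, rounded on write; round-trip is exact
  by construction and asserted as a property test.
* The strictly-greater hypergeometric tail $P(X > f_{11})$ is kept as
  the default (the observed table excluded); `inclusive = TRUE` gives the conventional one-sided Fisher
  tail. The error-model variance uses the population divisor $P$, not
  $P - 1$.
* The reproduction regression appends a point at the origin before
  fitting, which anchors the no-intercept line when scores cluster;
  $r^2$ is clamped to $[0, 1]$ at numerical boundaries.
* Empty paths score $f$ alone; all-gap columns get $\tilde Q = 0$;
  raising the quality cutoff can only shrink the FOLD set (asserted).

## Known limitations

Only the HMMER2 ASCII dialect is parsed; native HMMER3 files must be
converted externally (`hmmconvert -2`), mirroring the workflow the
method was designed around, with the documented loss of local
entry/exit parameters. The HMMER2 text-output parser assumes glocal
alignments starting at model position 1. Fisher p-values across many
domains are reported raw; multiple-testing correction is left to the
caller. Resolving which search engine is "better" is explicitly out of
scope — engine tags are free-form strings throughout.
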