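---
title: "Methods: shRNAmir design rules and co-expression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shRNAmir design rules and co-expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmirtools)
```

This vignette is the package's own account of the science it
implements: the design rules for microRNA-embedded shRNAs, the ordinal
co-expression statistics, the image-quantification conventions, and
the generative model behind the synthetic data, together with the
numerical choices made where the published procedures leave room.

## Guide design

### The off-target rule and its operational definition

A candidate guide is rejected when its target window has *more than
15 nt of contiguous complementarity* to any transcript other than the
target's own isoforms. Two readings of "complementarity" are possible:
a contiguous exact duplex, or a mismatch-tolerant total. We implement
the contiguous reading, for two reasons: it admits an exact and fast
screen, and it is the stricter interpretation of a published threshold
stated without a mismatch allowance. Mismatch-tolerant scanning is an
explicit non-goal.

With the contiguous reading, the rule has a useful identity: a window
has a contiguous match longer than 15 nt to a transcript **iff** it
shares a 16-mer with it. The screen therefore indexes all 16-mers of
the non-target transcriptome (`buildKmerIndex`, `seedK = 16 =
threshold + 1`) and rejects a window iff any of its seven 16-mers
hits the index. `maxComplementarityRun` computes the exact run length
by dynamic programming (`longestCommonSubstring`) and is the reference
the screen is tested against; the test suite checks the decision
identity exhaustively on fixtures with planted runs of 14–17 nt.

Two orientation decisions are folded into this screen. The guide
(antisense) strand is complementary to the mRNA, so "guide shares k nt
of complementarity with transcript t" is evaluated as "the sense
target window shares a k-mer with t" — identical by reverse-complement
symmetry, and it avoids double-complementing. And only the sense (mRNA)
strand of transcripts is screened, since RNAi acts on mRNA.

The screen runs on the 22-nt *pre-mismatch* window: that is the
sequence actually complementary to transcripts; the engineered
first-position mismatch does not pair with the target.

### 21 → 22 nt duplex construction

DSIR-style candidates are 21-mers with 2-nt 3′ overhangs. The mirE
scaffold wants a blunt, fully overlapping 22-nt duplex. We construct it
as: `sense22_raw = target[start − 2, start + 20)` — one base trimmed
from the candidate's 3′ end, two bases of *upstream target context*
added at the 5′ end — and `antisense22 = revcomp(sense22_raw)`. The
published procedure does not say where the added bases come from;
extension from target context is the only choice consistent with a
fully overlapping duplex whose antisense strand remains perfectly
complementary to the mRNA, and it is the reason enumeration starts at
position 2 (windows without two upstream bases are inadmissible, so a
target of length L yields L − 22 candidates).

The sense mismatch mimics the endogenous miR-30a duplex: position one
of the sense strand maps C→A, G→A, A→C, T→C; all other positions are
untouched. The map is total over the DNA alphabet and verified
exhaustively.

### Ranking

The regression model of the external DSIR webtool is deliberately not
reproduced; ranking is a strategy slot. The default heuristic awards
one point for GC fraction within [0.30, 0.65] plus a thermodynamic
asymmetry proxy (AT fraction of the last four sense bases minus the
first four, favouring guides whose antisense 5′ end unwinds easily) —
enough to produce stable, plausible orderings on fixtures. Externally
computed scores can be injected as a numeric vector, which is the
intended path when a DSIR ranking is available. Ties break by smaller
start, then lexicographic sequence, so ranking is a total
deterministic order. The pipeline filters a fixed ranked list; it does
not re-rank after filtering.

### Scaffolds and constructs

Scaffold templates are data, not code: an ordered alternation of fixed
blocks and `sense_i`/`antisense_i` slots, editable as YAML. The
shipped mirE template uses the standard miR-30a-derived context (5′
arm `TGCTGTTGACAGTGAGCG`, miR-30 loop `TAGTGAAGCCACAGATGTA`, 3′ arm
`TGCCTACTGCCTCGGA`). The four-hairpin polycistronic template shipped
as `mir17-19b_synthetic_template.yaml` is a *synthetic stand-in*: its
hairpin layout (four sense/antisense slot pairs joined by spacers) is
the real structure, but the arm/loop/spacer blocks are placeholders to
be replaced with the true mir17-19b context when available. The
assembly logic is independent of block content, so the substitution is
a data edit.

Construct assembly concatenates promoter, ORF, the 5′ flank (BsrGI
`TGTACA`, then AscI `GGCGCGCC`), the scaffold insert, the 3′ flank
(SalI `GTCGAC`) and any downstream backbone remainder, then validates
that each declared recognition site occurs exactly once in the final
sequence — a site re-created inside the insert would break single-cut
cloning, and the error lists the offending 0-based positions.
Recognition sequences are configuration, not constants. Coordinates
are 0-based half-open everywhere in the package; the flat-file writer
converts to 1-based inclusive, as flat-file convention demands.

## Ordinal co-expression statistics

Marker categories are scored strong = 1, medium = 2, weak = 3;
reporter categories RU = 1 (untreated) through RS = 5 (strong
reporter). With these orientations an *inverse* expression relation —
more reporter, less marker — yields a *positive* trend statistic. When
comparing against externally reported values whose score convention is
unknown, compare |Z|.

The linear-by-linear association test is the package's own
implementation: T = Σ uᵢvⱼnᵢⱼ, r = the score correlation over the n
cells, Z = r·√(n − 1), two-sided p from the standard normal. The
identity between this closed form and the permutation-standardized
statistic is exact; the test suite additionally checks the asymptotic
p against a 10⁵-replicate permutation oracle (mid-p convention, since
the integer-scored statistic has substantial tie mass at small n). A
Z statistic has one degree of freedom; the conventional table df
(r−1)(c−1) and the equivalent 1-df chi-square Z² are reported as
metadata because ordinal-table results are sometimes printed with
either convention. Degenerate tables (a single nonzero row or column)
are an error, not a silent zero.

The goodness-of-fit test compares treated category counts to untreated
reference ratios with the standard X² statistic on df = categories − 1
(delegated to `chisq.test`), with no continuity correction — both
tests are asymptotic by design, matching how such tables are normally
analysed. Reference ratios estimated from a finite untreated sample
are treated as fixed; the calibration test therefore uses an untreated
pool an order of magnitude larger than the treated sample, which keeps
the inflation from reference estimation below the Monte-Carlo
resolution. No multiple-testing correction is applied across
constructs for the categorical tests; the image-side KS test takes an
*explicit* Bonferroni family size m, with no hidden default, because
the appropriate family depends on the panel being assembled.

Density comparisons use the Wilcoxon–Mann–Whitney test: exact
enumeration when both groups have ≤ 8 regions and no ties,
tie-corrected normal approximation without continuity correction
otherwise; completely tied data return p = 1. Penetrance counts
reporter level ≥ RW as positive: RN means "reporter not detected", so
it must count as negative.

## Image quantification

Intensities are 8-bit gray levels (0–255). Background normalization
scales the frame so the mean over the background mask hits the target
(≈100 marker, ≈10 reporter); values pushed past 255 are clamped so the
image stays 8-bit, and the clamped-pixel count is recorded on the
object since heavy clamping signals an inappropriate target. The
reporter background mask (regions away from the injection site) is
supplied explicitly, never inferred. Per-cell means subtract the
background and floor at 0 — negative brightness is physically
meaningless. Whether a floor was applied in the published analysis is
unstated; we floor both channels for symmetry.

IoU evaluation must match predicted to truth objects before scoring;
the matching rule is not standardized, so we use greedy descending
overlap (each object used once), record the assignment, and score
unmatched truth objects 0, averaging over truth objects. Greedy
matching is the common choice in segmentation benchmarks and is
reported alongside the assignment so alternative matchers can be
compared. The baseline segmenter is deliberately naive —
threshold + 8-connected components + minimum area — because the
package consumes label masks from *any* segmenter; the baseline exists
so the IoU machinery and the rendered synthetic images can validate
each other (mean IoU ≥ 0.7 on well-separated renders, the working
definition of a good segmentation here).

## The synthetic generative model

`simulateCellTable` encodes the study conditions the analyses assume:
region densities uniform in 8–15 cells/mm², untreated
strong/medium/weak proportions 0.30/0.60/0.10, penetrance 0.80.
Latent marker intensity is drawn by sampling the category at the
baseline proportions and then uniformly within that category's
intensity band (bands 30–80–150–220); measurement noise (σ = 5 gray
levels) is added before re-thresholding, so observed proportions drift
from the baseline only by the small boundary flux. Treated cells
receive, with probability equal to the penetrance, a normalized
reporter dose R ~ Beta(2, 2) — the dose–response form is unconstrained
by any published value, so it is explicit configuration — and their
marker intensity becomes C·(1 − βR) + ε with β ∈ [0, 1]. Reporter
intensity is 200·R + λ·C + ε; λ (default 0.05) is the linear leakage
of marker signal into the reporter channel, which reproduces the
small positive marker–reporter correlation seen in untreated regions.
Category thresholds are generator configuration, not estimates:
annotators' visual thresholds are unknowable, and all acceptance
checks work on proportions, not thresholds.

What the generator does *not* emulate: loss of detectable cells under
strong knockdown (so simulated densities do not drop with β, unlike
the strongest published construct), spatial anatomy beyond a jittered
grid of elliptical cells, multi-channel bleed-through beyond the
single linear λ term, and inter-animal variation (counts are pooled,
as in the analyses the package supports). Passing tests therefore
demonstrate the correctness of the statistics and the screening
machinery under a known generative model — not that real histology
satisfies that model.

Parameter recovery closes the loop: β̂ = −b/a from the least-squares
fit C′ = a + bR over treated cells (consistent because a estimates the
baseline mean and b estimates −β times it; CI by the delta method),
and λ̂ as the reporter-on-marker regression slope over untreated
cells. Across 50 replicate simulations at ~5,000 cells, the mean β̂
lands within ±0.05 of the planted β = 0.5.

## Problem sizes and determinism

Every generator takes an explicit seed and is byte-reproducible. The
test suite and the acceptance script use desk-scale sizes chosen to
make the statistical checks decisive while remaining quick: ~650
windows against 12 decoys for the screen-vs-oracle identity, 20 random
tables × 10⁵ permutations for the trend-test oracle, 10⁴ replicates
for type-I calibration, 50 replicate simulations for slope recovery,
and 10⁴ untreated cells for the baseline-proportion check. Degenerate
inputs (empty tables, zero-variance vectors, empty masks, missing
upstream context, too-short targets) raise informative errors rather
than propagating NaN.

## Known limitations

* The DSIR scoring model is not reproduced; the default scorer is an
  avowed heuristic, and externally supplied scores are first-class.
* Off-target screening is exact only under the contiguous reading;
  seed-region (positions 2–8) match counting is out of scope.
* The polycistronic template ships with synthetic placeholder blocks.
* No hairpin folding or ΔG validation; no gapped alignment; no
  genome-scale index structures (the k-mer set is held in memory,
  appropriate for transcriptome-scale inputs).
* The published in-vivo statistics can only be recomputed once the
  underlying raw per-region count tables are transcribed into
  `inst/extdata`; the machinery is in place and unit-tested, and the
  acceptance suite marks that recomputation as unmet until the data
  file exists.
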