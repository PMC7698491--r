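---
title: "Inferring a phage transcriptional landscape from stranded coverage"
author: "phagetu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a phage transcriptional landscape from stranded coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetu)
```

# The inference problem

A strictly lytic phage runs its genome as a timed program: *early*
transcription units (TUs) are served by the host RNA polymerase from
sigma-70-type promoters within minutes of injection, and *late* units —
largely structural genes — switch on in the late phase, under a promoter
class with a long -10 element and no -35 box, presumed to be read via a
phage-encoded sigma factor. The observable is a set of strand-specific
coverage tracks, one per strand per timepoint. `phagetu` turns those
tracks plus an ORF annotation into: TSS and TTS calls, trained early and
late promoter models with a genome-wide rescan, Rho-independent
terminator calls with readthrough estimates, normalized expression with
temporal gene classes, and an assembly of everything into early / late /
dual transcription units.

All internal coordinates are 0-based and half-open. A coverage *step*
position is the boundary index between the bases to its left and right;
for a plus-strand unit the TSS boundary equals the index of the first
transcribed base, and the same convention mirrored applies on the minus
strand. GFF3 (1-based, inclusive) is converted only at the I/O boundary;
bedGraph is natively 0-based half-open and read with overlapping
intervals rejected rather than summed, since silent summation hides
malformed exports.

# Step detection

At every admissible boundary `p` the detector compares mean depth over
`[p−w, p)` and `[p, p+w)` and scores
`fold = (high + ε) / (low + ε)`. Candidates require `fold ≥ min_fold`
and a high-side mean of at least `min_high_depth`; the strongest
candidate suppresses weaker same-direction neighbours within
`max(merge_distance, w)` — at least `w`, because the two-window statistic
has support width `w` and a strong boundary casts secondary
above-threshold candidates up to `w − 1` bp away that are not distinct
steps. Defaults: `w = 50`, `min_fold = 2`, `min_high_depth = 10`,
`merge_distance = 25`, `ε = 1`.

`min_fold = 2` deserves a note. Under the negative-binomial noise the
package simulates (dispersion 0.1 at depths of tens to hundreds), the
coefficient of variation of a 50 bp window mean is a few percent, so a
twofold contrast sits dozens of standard deviations above noise; the
binding constraint is instead biological: an internal promoter firing
inside an already-transcribed unit only raises coverage by its own
contribution, so requiring threefold would systematically discard
internal promoters that merely double local depth. Promoters
contributing less than about 1.5-fold remain undetectable by coverage
alone and are only recoverable as motif matches.

Timing follows the pooled-early rule: a step found at either of the
first two timepoints is *early*; a step found only at the last timepoint
is *late*; a position detected both early and late stays early, since
transcription started earlier and is merely ongoing.

A late promoter inside an early unit is nearly invisible on the raw
late-phase track because early transcription still runs through it. The
diagnostic signal is a step in the *ratio* of late-phase to pooled
early-phase coverage: flat across a unit transcribed at constant
relative intensity, but jumping where depth is added only late. The
pipeline therefore also scans this ratio (with the same fold and an
absolute late-excess floor) and adds ratio up-steps that no timed step
already explains as late TSS candidates.

# Promoter models

100 bp windows upstream of early up-steps (reverse-complemented for
minus-strand steps, so they always read 5'→3' toward the TSS) train the
early model in two stages. First, ZOOPS expectation–maximisation — zero
or one site per window, site prior estimated, best of 20 restarts,
convergence at a log-likelihood gain below 1e-6 — locates an 11-column
block covering the extended -10 element (`TRTGN` + `TATANT`). EM can
converge with the alignment laterally shifted, a well-known local
optimum, so the fit is refined by re-seeding from the maximum-posterior
sites shifted ±1–3 columns and keeping the best re-run. Second, the -35
hexamer is aligned upstream of each located block over the allowed
spacers {16, 17, 18} (distance from the -35 3' end to the -10 5' start;
the extension occupies the spacer's last 5 nt), iterating the per-site
spacer choice against the evolving -35 matrix. Spacer penalties are 0
bits for 17 and 1.5 bits for 16/18, reflecting how rarely the long and
short forms occur. Late windows train a single width-10 PWM the same
way. Training windows are sorted lexicographically before fitting so
that seeded discovery does not depend on the genomic orientation the
windows were collected in.

PWMs use a Laplace pseudocount of 1 and, during discovery, the windows'
own mononucleotide composition as background. The rescan threshold
implements the training-recovery rule: the minimum score over the
training sites, so the scan provably retrieves 100% of the sequences the
matrix was built from. The total early-model score is
`score(-35) + score(ext + -10 block) − spacer_penalty`, maximised over
spacers per position; the TSS is placed 6 bp downstream of the -10 box
3' end. Same-strand hits within 5 bp collapse to the best score (ties to
the leftmost); palindromic matches are deliberately reported on both
strands.

Scan hits and coverage steps are then reconciled one-to-one: pairs are
matched greedily by distance (within 25 bp), so each step supports
exactly one call and each call is claimed by at most one step. This
keeps secondary motif matches from riding along on a true promoter's
coverage evidence, and lets two adjacent steps — an early TSS with a
late promoter 25 bp downstream, the geometry of a compact dual unit —
keep their identities in either genome orientation. Unclaimed steps
become step-only promoter calls; unclaimed scan hits are kept as
*rescues*, marked coverage-supported only when a relaxed-threshold step
(`min_fold = 1.5`, `min_high_depth = 5`) sits nearby, and otherwise
flagged inactive: motif matches that do not change the transcription
profile. Recovery metrics treat sensitivity over all calls but precision
over the coverage-supported ones, mirroring how predictions without
transcriptional support are reported apart from the active set.

The IUPAC consensus of a column is the single majority base when its
probability is at least 0.5 and twice the runner-up, a two-base code
when the top two sum to at least 0.75, else `N`. One property of ZOOPS
discovery is worth knowing: on i.i.d. random windows the best alignment
still carries residual information — pure selection bias over the
offsets in each window, about 0.55 bits/column at 90–100 bp windows and
below 0.5 at 40 bp. The null test probes the short-window regime, where
a genuine motif (≈2 bits/column) is still unmistakable.

# Terminators

Windows of ±50 bp around down-steps, oriented in transcription
direction, are searched by exhaustive stem-loop enumeration: all
placements with stem length 5–15, loop 3–9 and at most one mismatch,
scored `2·(G:C pairs) + 1·(A:T or G·U pairs) − 3·mismatches −
0.1·loop_len`, with G·U counted as a weak pair because the structure
acts at RNA level. Enumeration replaces thermodynamic folding
deliberately: the calling criterion is structural — a GC-rich stem-loop
followed by a polyT tract — not an energy threshold, and enumeration is
exact, dependency-free and directly testable against a brute-force
oracle. A call requires the best hairpin to reach `min_score = 8` *and*
a run of at least 4 T's (one internal non-T tolerated) starting within
3 nt of the stem's 3' side; a hairpin without the tract, or a tract
without the hairpin, is not a terminator. Readthrough is the mean depth
over the 100 bp downstream of the boundary divided by the 100 bp
upstream, in transcription direction, clamped to [0, 1] and reported as
NA when the upstream side is essentially uncovered (mean < 1), where the
ratio would be meaningless.

# Expression

TMM normalization is implemented natively at pairwise granularity:
per-gene log-ratios (M) and log-abundances (A) on library-scaled counts,
zeros excluded, two-sided trimming of 30% on M and 5% on A, and an
inverse asymptotic-binomial-variance weighted mean of the retained M
values; per-sample factors are rescaled to geometric mean 1, with the
reference sample chosen by the upper-quartile rule. The test suite
verifies equality with an independent step-by-step oracle to 1e-10 and
cross-checks against edgeR's implementation. GeTMM applies TMM to
reads-per-kilobase values and scales each sample to per-million of its
effective RPK library, so values compare across samples and across genes
of different length. Non-coding regions are quantified alongside ORFs as
pseudo-genes with their own lengths.

Differential calls use an exact conditional test: with a common
negative-binomial dispersion φ (method-of-moments, pooled across genes
on library-equalized counts) and equal means under the null, the group-A
sum conditioned on the total follows a negative hypergeometric law free
of the mean — the double-tail probability is summed directly, and φ = 0
degenerates to the conditional binomial, which also covers the
single-replicate case. The full empirical-Bayes tagwise-dispersion
machinery of dedicated DE packages is intentionally not reproduced: the
load-bearing parts here are the normalization and the FDR ≤ 0.01 rule,
and the exact conditional test is conservative under the null (the
suite measures an empirical flag rate well below 0.02 at nominal 0.01)
with essentially full power for fourfold induction at three replicates
and dispersion 0.05. BH adjustment uses `stats::p.adjust`; the hand
cumulative-minimum construction serves as its oracle in tests. Genes
with zero counts everywhere are dropped before normalization; 0.5 is
added inside the log-fold-change display only.

A gene is *late-expressed* when significantly up at the last timepoint
versus the pooled earlier ones and essentially silent at the first
timepoint (below the 0.2 quantile of positive first-timepoint values,
floored at 1); *early-expressed* when expressed at the first timepoint;
*flat* otherwise.

# TU assembly

Each strand is walked 5'→3'. A TU opens at the first active promoter
not inside an open unit, extends over co-oriented ORFs, and closes at
the first terminator that follows at least one ORF and whose late-phase
readthrough is below 0.5 — above that, transcription is treated as
continuing and the terminator is recorded inside the unit. Promoters met
inside an open unit become internal promoters; a promoter with no ORF
before the closing terminator is an orphan and forms no unit (the
highly expressed non-coding regions end up here by design); ORFs
upstream of every promoter on their strand stay unassigned rather than
being forced into units. A unit is *early* iff all its promoters are
early, *late* iff all are late, *both* otherwise. Strands are treated
fully independently, and reported spans run TSS → terminator boundary.

# What the simulator emulates — and what it does not

The generator is the package's ground truth and mirrors the biology the
inference assumes. Defaults: a 50 kb AT-rich genome (GC 0.35) with 12
non-overlapping TUs on both strands (plus-strand probability 20/35) and
two highly expressed non-coding regions; TU temporal classes drawn as
early : late : dual = 26 : 4 : 5; 1–6 ORFs of 200–800 bp per TU;
promoter cassettes sampled from their IUPAC consensus with a 2%
per-position mutation rate (spacers 17 bp with probability 0.9, 16/18
with 0.05 each; the late downstream TT planted as an 85% enrichment —
planting it literally would leave the core's alignment phase degenerate
over a 12 nt conserved run); terminator stems realizing their GC
fraction exactly, with readthrough drawn in [0.02, 0.25]. Early promoter
strengths are log-uniform on [60, 350] expected reads/base, late on
[250, 700], echoing the late phase's dominance of the transcriptional
output. Expected depth is the sum of active promoter strengths
downstream of each TSS, attenuated multiplicatively at each terminator;
readthrough tails decay with a 300 bp processivity length so leakage
stays local instead of running out along the genome. Transcript aging
causes 5'-biased depletion: a promoter's contribution is damped by
`exp(−rate · age · d₃/1000)` with `rate = 0.2` per kb per timepoint
step, `age` the timepoints since the promoter became active (so late
transcripts are fresh in the late phase) and `d₃` the distance to the
closing terminator — which reproduces the hallmark that late-versus-early
coverage differences grow toward unit 3' ends. Per-base noise is
negative-binomial with dispersion 0.1; dispersion 0 switches the
generator into an exact regime (coverage equals its expectation, counts
equal their rounded means) used by the closed-form tests. Counts per ORF
are NB draws with mean = mean expected depth × length / 100 (one read
per 100 bp of depth), with mild lognormal library-size jitter. The
absolute depth scale is not dictated by any published value and is
exposed as configuration.

Deliberately not modelled: read-level simulation (the inference consumes
coverage, and reads add no testable structure), the host transcriptome
and its progressive takeover, tRNA genes, self-splicing introns,
sequence-dependent library biases, and TUs overlapping on opposite
strands. Passing the recovery tests therefore demonstrates correctness
of the inference logic under the stated generative assumptions — step
geometry, motif grammar, hairpin+polyT structure, NB noise — not
robustness to artifacts these simplifications exclude (mapping bias,
rRNA carry-over, coverage dips inside units, promoter grammars unlike
the planted one).

# Problem sizes and determinism

The shipped tests and the acceptance script run at the scale the
package targets: a 50 kb genome with 12 TUs and three timepoints for
end-to-end recovery (noisy and noiseless variants), 36 early / 12 late
training windows for consensus recovery, 200–500 replicate simulations
for the differential test's calibration and power, and brute-force
oracle comparisons (PWM scanning, hairpin enumeration, TMM, GeTMM, BH)
on randomized small instances at 1e-10. Every stochastic step takes an
explicit seed; the same seed reproduces genomes, coverage, counts and
fitted models bit-identically, and all randomness is restored-state
local so library calls do not perturb the caller's stream.

# Known limitations

* Promoters contributing less than ~1.5-fold over running-through
  transcription are invisible to coverage and recoverable only as motif
  matches; if such a site also scores below the training-recovery
  threshold, it is missed.
* The training-recovery threshold is generous by construction (it must
  retrieve the weakest training site), so genome-wide rescans produce
  speculative hits; these are reported, flagged inactive, and excluded
  from the active set rather than suppressed.
* Readthrough estimates at later timepoints absorb some 5'-depletion
  signal into the upstream mean; the exactness guarantee holds in the
  undegraded regime.
* The terminator score is additive and structural; it does not rank
  terminator *strength*, only presence.
* TUs sharing a terminator from opposite strands are resolved
  independently per strand; convergent architecture is not arbitrated.
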