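# phagetu

Transcriptional landscape inference for lytic bacteriophages from
strand-specific RNA-seq coverage.

During a lytic infection a phage reorganizes its host's transcription in
minutes: *early* genes are read by the host RNA polymerase from
sigma-70-type promoters immediately after injection, while *late* genes
(mostly virion morphogenesis) switch on only in the late phase, typically
under a phage-encoded sigma factor that recognizes a different promoter
class. Given stranded coverage tracks from a few timepoints
post-infection, `phagetu` reconstructs this architecture:

* **TSS/TTS calling.** Transcription start and termination sites are
  detected as sharp up-/down-steps of strand-specific coverage: a
  two-window fold test at every genomic boundary,
  `fold = (high + ε)/(low + ε)` over `w` bp flanks, with local-maximum
  selection. Steps seen in the pooled early timepoints are *early*; steps
  appearing only at the last timepoint — including steps of the ratio of
  late to early coverage, which expose late promoters firing inside
  already-transcribed units — are *late*.
* **Promoter models.** 100 bp windows upstream of early TSSs train a
  two-box sigma-70 model by ZOOPS (zero-or-one site per window)
  expectation–maximisation: a -35 hexamer (consensus `TTGACW`) and an
  11-column extended -10 block (`TRTGN` + `TATANT`) separated by a
  16–18 bp spacer, with the TSS 6 bp downstream of the -10 box. Late
  windows train a single long -10 PWM (consensus `TGTTATATTA`). Each
  model rescans both strands of the genome with its score threshold set
  to retrieve every training site; hits without coverage support are
  reported but flagged inactive.
* **Terminators.** Windows around down-steps are searched exhaustively
  for GC-rich stem-loops (score `2·GC + 1·(AT/GU) − 3·mismatch −
  0.1·loop`) followed by a polyT tract; readthrough is estimated per
  timepoint as the downstream/upstream coverage ratio.
* **Expression.** Count matrices are normalized by TMM and gene-length
  corrected (GeTMM); differential calls use an exact conditional
  negative-binomial test with a method-of-moments common dispersion and
  Benjamini–Hochberg FDR ≤ 0.01; genes are classed early-expressed,
  late-expressed or flat.
* **Transcription units.** Promoters, terminators and ORFs are walked
  strand-wise 5'→3'; a terminator closes its unit when its late-phase
  readthrough is below 0.5; each TU is classed *early*, *late* or *both*
  from its promoter classes.

A first-class synthetic-data module (`generate_architecture`,
`plant_sequence`, `simulate_coverage`, `simulate_counts`) plants known
regulatory architectures — promoter cassettes sampled from their
consensus, revcomp-paired hairpins with polyT tracts, negative-binomial
coverage noise, terminator readthrough with finite processivity, and
5'-biased transcript decay at later timepoints — so that every stage of
the pipeline is validated by recovering what was planted.

## Worked example

```r
library(phagetu)

params <- sim_params()                       # 50 kb genome, t5/t15/t30
arch   <- generate_architecture(n_tus = 12, params, seed = 1)
genome <- plant_sequence(arch, params, seed = 2)
tracks <- simulate_coverage(arch, params, seed = 3)

res <- infer_landscape(genome, arch$orfs, tracks, params$timepoints, seed = 4)
res
#> <phage_landscape> 19 promoter calls ( 17 active ), 14 terminators, 12 TUs
res$early_model
#> <early_promoter_model> -35 TTGACW | ext+-10 TRTGNTATANT | spacers 16/17/18 | threshold 19.02
res$late_model
#> <pwm_model> width 10 from 6 sites; consensus TGTTATATTA
res$report$by_class
#>       level n percent
#> early early 7    58.3
#> late   late 4    33.3
#> both   both 1     8.3
evaluate_promoter_recovery(arch, res$promoters)[c("sensitivity", "precision")]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 1
```

All 12 planted units are reassembled with their temporal classes; the
discovered consensus strings match the planted promoter grammar, and
every planted promoter is recovered with no false active call. Counts
work the same way:

```r
counts <- simulate_counts(arch, params, n_replicates = 3, seed = 5)
norm   <- getmm(counts)                       # TMM + gene-length correction
round(region_fraction(norm, c("lncRNA1", "lncRNA2")), 1)
#> [1] 10.2
```

i.e. the two planted highly expressed non-coding regions absorb ~10% of
all normalized expression in this simulation.

A thin command-line front end is installed under `inst/cli/phagetu`,
with `synth` (write a simulated dataset: FASTA, GFF3, bedGraphs, counts,
truth tables) and `landscape` (run the full inference from those files)
subcommands.

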