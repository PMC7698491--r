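# The generator must place what it promises: exact motif instances,
# revcomp-planted minus-strand elements, closed-form noiseless coverage
# and seed-reproducible everything.

test_that("same seed reproduces genome, coverage and counts bit-identically", {
  p <- sim_params(genome_length = 20000L)
  d1 <- simulate_dataset(4, p, seed = 9)
  d2 <- simulate_dataset(4, p, seed = 9)
  expect_identical(d1$genome$sequence, d2$genome$sequence)
  expect_identical(d1$tracks[["t30.+"]]$depth, d2$tracks[["t30.+"]]$depth)
  expect_identical(d1$counts$counts, d2$counts$counts)
  d3 <- simulate_dataset(4, p, seed = 10)
  expect_false(identical(d1$genome$sequence, d3$genome$sequence))
})

test_that("architecture respects class mix, counts and genome capacity", {
  p <- sim_params(genome_length = 300000L)
  arch <- generate_architecture(60, p, seed = 2, n_regions = 0L)
  expect_equal(nrow(arch$tus), 60L)
  frac <- table(factor(arch$tus$class, c("early", "late", "both"))) / 60
  expect_true(abs(frac[["early"]] - 26 / 35) < 0.15)
  expect_true(abs(frac[["late"]] - 4 / 35) < 0.12)
  expect_true(abs(frac[["both"]] - 5 / 35) < 0.12)
  # every TU: 1-4 promoters, >= 1 terminator, >= 1 ORF
  for (tu in arch$tus$id) {
    expect_gte(sum(arch$promoters$tu == tu), 1L)
    expect_lte(sum(arch$promoters$tu == tu), 4L)
    expect_gte(sum(arch$terminators$tu == tu), 1L)
    expect_gte(sum(arch$orfs$tu == tu), 1L)
  }
  expect_error(generate_architecture(40, sim_params(genome_length = 20000L),
                                     seed = 1),
               "genome too short")
})

test_that("with mutation rate 0 every planted element is literally present", {
  p <- sim_params(genome_length = 30000L, mutation_rate = 0)
  arch <- generate_architecture(6, p, seed = 21)
  g <- plant_sequence(arch, p, seed = 22)
  sub0 <- function(a, b) substr(g$sequence, a + 1, b)
  rc <- reverse_complement
  iupac_ok <- function(s, pat) {
    grepl(paste0("^", chartr("RWN", "...", pat), "$"), s) &&
      all(mapply(function(ch, pc) {
        pc == "." || ch == pc ||
          (pc == "R" && ch %in% c("A", "G")) ||
          (pc == "W" && ch %in% c("A", "T")) ||
          (pc == "N")
      }, strsplit(s, "")[[1]], strsplit(pat, "")[[1]]))
  }
  pr <- arch$promoters
  for (i in seq_len(nrow(pr))) {
    T <- pr$tss[i]
    if (pr$class[i] == "late") {
      core <- if (pr$strand[i] == "+") sub0(T - 15, T - 5) else rc(sub0(T + 5, T + 15))
      expect_equal(core, "TGTTATATTA")
      # the upstream TWN element is planted from its consensus; the
      # downstream TT is an enrichment, not asserted literally
      twn <- if (pr$strand[i] == "+") sub0(T - 18, T - 15) else rc(sub0(T + 15, T + 18))
      expect_true(iupac_ok(twn, "TWN"))
    } else {
      s <- pr$spacer[i]
      m10 <- if (pr$strand[i] == "+") sub0(T - 11, T - 5) else rc(sub0(T + 5, T + 11))
      expect_true(iupac_ok(m10, "TATANT"))
      ext <- if (pr$strand[i] == "+") sub0(T - 16, T - 11) else rc(sub0(T + 11, T + 16))
      expect_true(iupac_ok(ext, "TRTGN"))
      a35 <- T - 11 - s - 6
      m35 <- if (pr$strand[i] == "+") sub0(a35, a35 + 6) else
        rc(sub0(T + 11 + s, T + 11 + s + 6))
      expect_true(iupac_ok(m35, "TTGACW"))
    }
  }
  tr <- arch$terminators
  for (i in seq_len(nrow(tr))) {
    B <- tr$pos[i]; pt <- tr$polyT_len[i]
    st <- tr$stem_len[i]; lp <- tr$loop_len[i]
    cassette <- if (tr$strand[i] == "+") {
      sub0(B - pt - 1 - 2 * st - lp, B)
    } else {
      rc(sub0(B, B + pt + 1 + 2 * st + lp))
    }
    stem1 <- substr(cassette, 1, st)
    stem2 <- substr(cassette, st + lp + 1, 2 * st + lp)
    expect_equal(stem2, rc(stem1))
    expect_equal(substr(cassette, nchar(cassette) - pt + 1, nchar(cassette)),
                 strrep("T", pt))
  }
})

test_that("planted elements reject overlap", {
  p <- sim_params(genome_length = 30000L)
  arch <- generate_architecture(4, p, seed = 5)
  # force two promoters onto the same spot
  arch$promoters$tss[2] <- arch$promoters$tss[1]
  arch$promoters$strand[2] <- arch$promoters$strand[1]
  arch$promoters$class[2] <- arch$promoters$class[1]
  arch$promoters$spacer[2] <- arch$promoters$spacer[1]
  expect_error(plant_sequence(arch, p, seed = 6), "overlap")
})

test_that("noiseless coverage equals the closed-form plateau product", {
  p <- sim_params(genome_length = 15000L, dispersion = 0,
                  degradation_rate = 0, readthrough_decay = 1e12)
  arch <- generate_architecture(1, p, seed = 31, n_regions = 0L,
                                class_fractions = c(early = 1, late = 0, both = 0))
  tracks <- simulate_coverage(arch, p, seed = 32)
  pr <- arch$promoters[order(arch$promoters$tss), ]
  tm <- arch$terminators
  strand <- pr$strand[1]
  trk <- tracks[[paste0("t5.", strand)]]
  S <- sum(pr$strength)
  primary_tss <- if (strand == "+") min(pr$tss) else max(pr$tss)
  # plateau between the last promoter and the terminator carries the sum
  # of all strengths; past the terminator the readthrough fraction remains
  covered <- if (strand == "+") c(max(pr$tss), tm$pos) else
    c(tm$pos, min(pr$tss))
  inner_bases <- (covered[1] + 5):(covered[2] - 5)       # 0-based
  expect_true(all(abs(trk$depth[inner_bases + 1] - S) < 1e-9))
  tail_bases <- if (strand == "+") (tm$pos + 5):(tm$pos + 60) else
    (tm$pos - 61):(tm$pos - 6)
  expect_true(all(abs(trk$depth[tail_bases + 1] - S * tm$readthrough) < 1e-6))
  # upstream of the primary promoter there is no signal
  outside_base <- if (strand == "+") primary_tss - 10 else primary_tss + 10
  expect_equal(trk$depth[outside_base + 1], 0)
  expect_equal(tracks[[paste0("t30.", strand)]]$depth, trk$depth)
})

test_that("late promoters contribute nothing before the last timepoint", {
  p <- sim_params(genome_length = 15000L, dispersion = 0)
  arch <- generate_architecture(1, p, seed = 41, n_regions = 0L,
                                class_fractions = c(early = 0, late = 1, both = 0))
  tracks <- simulate_coverage(arch, p, seed = 42)
  strand <- arch$tus$strand[1]
  expect_true(all(tracks[[paste0("t5.", strand)]]$depth == 0))
  expect_true(all(tracks[[paste0("t15.", strand)]]$depth == 0))
  expect_gt(max(tracks[[paste0("t30.", strand)]]$depth), 0)
})

test_that("5' depletion grows toward TU 5' ends at later timepoints", {
  p <- sim_params(genome_length = 15000L, dispersion = 0,
                  readthrough_decay = 1e9)
  arch <- generate_architecture(1, p, seed = 51, n_regions = 0L,
                                class_fractions = c(early = 1, late = 0, both = 0))
  tracks <- simulate_coverage(arch, p, seed = 52)
  tu <- arch$tus
  mid <- floor((tu$start + tu$end) / 2)
  five <- if (tu$strand == "+") tu$start + 30 else tu$end - 30
  three <- if (tu$strand == "+") tu$end - 30 else tu$start + 30
  r5 <- tracks[[paste0("t30.", tu$strand)]]$depth[five] /
    tracks[[paste0("t5.", tu$strand)]]$depth[five]
  r3 <- tracks[[paste0("t30.", tu$strand)]]$depth[three] /
    tracks[[paste0("t5.", tu$strand)]]$depth[three]
  expect_lt(r5, r3)  # 5' end more depleted at 30 min
  expect_lt(r5, 1)
})

test_that("counts: exact at zero dispersion, length-proportional, MC mean", {
  p0 <- sim_params(genome_length = 30000L, dispersion = 0)
  arch <- generate_architecture(5, p0, seed = 61)
  c0 <- simulate_counts(arch, p0, n_replicates = 2L, seed = 62)
  expect_identical(c0$counts[, 1], c0$counts[, 2])   # deterministic replicates
  # Monte-Carlo: empirical mean over many replicates within 2 percent
  p1 <- sim_params(genome_length = 30000L, dispersion = 0.1)
  c1 <- simulate_counts(arch, p1, n_replicates = 2000L, seed = 63)
  t5cols <- c1$samples$timepoint == "t5"
  big <- names(which(c0$counts[, "t5_r1"] > 200))
  emp <- rowMeans(c1$counts[big, t5cols, drop = FALSE])
  expect_true(all(abs(emp / c0$counts[big, "t5_r1"] - 1) < 0.02))
})
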