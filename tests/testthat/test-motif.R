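# PWM construction, scoring, consensus, the training-recovery threshold
# rule, ZOOPS discovery and genome scanning.

test_that("build_pwm reproduces hand-computed scores", {
  # 4 copies of TATAAT, pseudocount 1, uniform background: every column
  # probability is 5/8, total score 6*log2((5/8)/0.25)
  pwm <- build_pwm(rep("TATAAT", 4), pseudocount = 1)
  expect_equal(pwm_score(pwm, "TATAAT"), 6 * log2((5 / 8) / 0.25),
               tolerance = 1e-12)
  # pseudocount 0, one site: 4 * log2(4) = 8 bits exactly
  pwm0 <- build_pwm("ACGT", pseudocount = 0)
  expect_equal(pwm_score(pwm0, "ACGT"), 8)
  expect_equal(sum(pwm_information(pwm0)), 2 * 4)  # 2 bits per column
  # background equal to the column probabilities: all log-odds zero
  pwmb <- build_pwm(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0,
                    background = rep(0.25, 4))
  expect_true(all(abs(pwmb$logodds) < 1e-12))
  expect_error(build_pwm(c("ACGT", "ACG")), "unequal")
  expect_error(build_pwm(character(0)))
})

test_that("training threshold is the minimum training-site score", {
  set.seed(3)
  sites <- replicate(6, draw_iupac("TTGACW"))
  pwm <- build_pwm(sites)
  th <- training_threshold(pwm, sites)
  expect_equal(th, min(pwm_score(pwm, sites)))
  expect_true(all(pwm_score(pwm, sites) >= th))
  expect_error(training_threshold(pwm, character(0)), "empty")
})

test_that("IUPAC consensus follows the majority / pair / N rules", {
  mk <- function(p) {
    # wrap a probability matrix as a pwm for consensus_iupac
    structure(list(prob = p, width = ncol(p)), class = "pwm_model")
  }
  p <- matrix(c(0.5, 0, 0, 0.5,      # A/T -> W
                0.25, 0.25, 0.25, 0.25,  # N
                0.9, 0.04, 0.03, 0.03,   # A
                0.45, 0.05, 0.45, 0.05), # A/G -> R
              4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(consensus_iupac(mk(p)), "WNAR")
  # sites drawn from TTGACW give back TTGACW
  set.seed(4)
  pwm <- build_pwm(replicate(40, draw_iupac("TTGACW")))
  expect_equal(consensus_iupac(pwm), "TTGACW")
})

test_that("ZOOPS EM recovers a planted late motif and rejects noise", {
  set.seed(6)
  wins <- replicate(20, {
    off <- sample(0:70, 1)
    paste0(rand_dna(off), "TGTTATATTA", rand_dna(80 - off))
  })
  pwm <- discover_motif(wins, width = 10, seed = 2)
  expect_equal(consensus_iupac(pwm), "TGTTATATTA")
  # scanning the training windows at the training threshold finds a site
  # in every window
  for (wseq in wins) {
    g <- genome_record("w", wseq)
    expect_gte(nrow(scan_genome(pwm, g)), 1L)
  }
  # i.i.d. uniform windows carry no motif: information stays low. The
  # residual IC of a ZOOPS alignment on random windows is pure selection
  # bias and grows with the number of offsets per window, so the null is
  # probed at short windows where a real motif would still shine through
  set.seed(7)
  null_wins <- replicate(40, rand_dna(40))
  pwm_null <- discover_motif(null_wins, width = 10, seed = 3,
                             n_restarts = 5)
  expect_lt(mean(pwm_information(pwm_null)), 0.5)
  expect_error(discover_motif(wins[1:3], width = 10), "at least 5")
  expect_error(discover_motif(wins, width = 200), "width exceeds")
})

test_that("identical windows align identically and deterministically", {
  wins <- rep(paste0(strrep("A", 30), "TGTGCGCAAT", strrep("A", 20)), 8)
  pwm1 <- discover_motif(wins, width = 10, seed = 5)
  pwm2 <- discover_motif(wins, width = 10, seed = 5)
  expect_identical(pwm1$logodds, pwm2$logodds)
  expect_equal(length(unique(pwm1$sites$sequence)), 1L)
})

test_that("genome scan equals the brute-force scorer exactly", {
  set.seed(8)
  sites <- replicate(8, draw_iupac("TRTGNTATANT"))
  pwm <- build_pwm(sites)
  g <- genome_record("g", rand_dna(3000, gc = 0.4))
  th <- 6
  hits <- scan_genome(pwm, g, threshold = th, collapse = 0)
  orc <- oracle_scan_pwm(pwm$logodds, g$sequence, th)
  # map oracle (strand, start) to the TSS convention used by scan_genome
  orc$tss <- ifelse(orc$strand == "+", orc$start + 11 + 5,
                    3000 - (orc$start + 11 + 5))
  key <- function(d) sort(paste(d$strand, d$tss))
  expect_equal(key(hits), key(orc))
  o <- order(paste(hits$strand, hits$tss))
  oo <- order(paste(orc$strand, orc$tss))
  expect_equal(hits$score[o], orc$score[oo], tolerance = 1e-10)
  # +Inf threshold returns nothing
  expect_equal(nrow(scan_genome(pwm, g, threshold = Inf)), 0L)
})

test_that("palindromic instances are reported on both strands", {
  pwm <- build_pwm(rep("GAATTC", 5), pseudocount = 0.01)
  g <- genome_record("g", paste0(strrep("A", 60), "GAATTC", strrep("A", 60)))
  hits <- scan_genome(pwm, g, threshold = 5)
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("the early model scores -35 + block - spacer penalty", {
  set.seed(9)
  pwm35 <- build_pwm(replicate(10, draw_iupac("TTGACW")))
  pwm10 <- build_pwm(replicate(10, draw_iupac("TRTGNTATANT")))
  model <- early_promoter_model(pwm35, pwm10, threshold = -Inf)
  # construct a perfect placement at spacer 17 and verify additivity
  m35 <- "TTGACA"; block <- "TATGATATAAT"
  win <- paste0(rand_dna(20), m35, rand_dna(12), block, rand_dna(10))
  sc <- phagetu:::score_early_placement(model, win, 20 + 6 + 12)
  expect_equal(sc$spacer, 17L)
  expect_equal(sc$score,
               pwm_score(pwm35, m35) + pwm_score(pwm10, block),
               tolerance = 1e-12)
  # a 16 bp spacer pays its penalty
  win16 <- paste0(rand_dna(20), m35, rand_dna(11), block, rand_dna(10))
  sc16 <- phagetu:::score_early_placement(model, win16, 20 + 6 + 11)
  expect_equal(sc16$spacer, 16L)
  expect_equal(sc16$score,
               pwm_score(pwm35, m35) + pwm_score(pwm10, block) - 1.5,
               tolerance = 1e-12)
})

test_that("early model training recovers consensus and all its sites", {
  set.seed(10)
  wins <- c(replicate(30, make_early_window(17L)),
            make_early_window(16L), make_early_window(18L))
  model <- build_early_model(wins, seed = 11)
  expect_equal(model$consensus$m35, "TTGACW")
  expect_equal(model$consensus$m10, "TATANT")
  expect_true(all(model$sites$score >= model$threshold))
  expect_setequal(unique(model$sites$spacer), c(16L, 17L, 18L))
})

test_that("promoter calls inherit step timing; rescues are flagged", {
  calls <- data.frame(tss = c(100, 500, 900), strand = "+",
                      score = c(10, 9, 8), spacer = NA, box10_start = NA,
                      box10_end = NA, source = "pwm",
                      class = c("early", "late", "late"))
  timed <- data.frame(position = c(102, 905), direction = "up", strand = "+",
                      fold = c(5, 7), high_side_depth = c(50, 60),
                      timing = c("early", "early"),
                      timepoints = c("t5", "t5"))
  out <- classify_promoter_class(calls, timed)
  expect_equal(out$class, c("early", "late", "early"))
  expect_equal(out$source, c("step", "pwm_rescue", "step"))
  expect_equal(out$active, c(TRUE, FALSE, TRUE))
})
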