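# Fixture builders and independent brute-force oracles. Everything here
# is deliberately written without reusing package internals, so the
# oracles stay independent of the code paths they check.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

draw_iupac <- function(pattern) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), W = c("A", "T"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    o <- tab[[ch]]
    if (length(o) == 1) o else sample(o, 1)
  }, character(1)), collapse = "")
}

# 100 bp window ending at the TSS with a planted early promoter cassette:
# -35, spacer (ext in its last 5 nt), -10, 5 nt to the window end.
make_early_window <- function(spacer = 17L) {
  pad <- rand_dna(83L - spacer)
  paste0(pad, draw_iupac("TTGACW"), rand_dna(spacer - 5L),
         draw_iupac("TRTGN"), draw_iupac("TATANT"), rand_dna(5L))
}

# 100 bp window with a planted late promoter block; the downstream TT
# extension is enriched (85% T) rather than invariant.
make_late_window <- function() {
  tt <- paste(ifelse(runif(2) < 0.85, "T", sample(c("A", "C", "G"), 2, TRUE)),
              collapse = "")
  paste0(rand_dna(82L), draw_iupac("TWN"), "TGTTATATTA", tt, rand_dna(3L))
}

# Exhaustive two-window step oracle: loops and sum(), no cumsum tricks.
oracle_steps <- function(depth, w, min_fold, min_high, eps, strand) {
  L <- length(depth)
  out <- NULL
  for (p in w:(L - w)) {
    left <- sum(depth[(p - w + 1):p]) / w
    right <- sum(depth[(p + 1):(p + w)]) / w
    hi <- max(left, right); lo <- min(left, right)
    fold <- (hi + eps) / (lo + eps)
    if (fold >= min_fold && hi >= min_high && left != right) {
      rising <- right > left
      dirn <- if (strand == "+") {
        if (rising) "up" else "down"
      } else {
        if (rising) "down" else "up"
      }
      out <- rbind(out, data.frame(position = p, direction = dirn,
                                   fold = fold))
    }
  }
  out
}

# Brute-force PWM scan of both strands of a genome string: per-position
# score by explicit per-letter lookup.
oracle_scan_pwm <- function(logodds, genome_seq, threshold) {
  width <- ncol(logodds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  hits <- NULL
  for (strand in c("+", "-")) {
    txt <- if (strand == "+") genome_seq else revcomp(genome_seq)
    ch <- strsplit(txt, "")[[1]]
    for (i in 0:(nchar(txt) - width)) {
      sc <- 0
      for (j in 1:width) sc <- sc + logodds[ch[i + j], j]
      if (sc >= threshold) {
        hits <- rbind(hits, data.frame(strand = strand, start = i, score = sc))
      }
    }
  }
  hits
}

# Brute-force hairpin enumeration with its own pairing logic.
oracle_hairpins <- function(seq, min_stem, max_stem, loop_min, loop_max,
                            max_mismatch, gu = TRUE) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pairs <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return("at")
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return("gc")
    if (gu && ((a == "G" && b == "T") || (a == "T" && b == "G"))) return("gu")
    "mm"
  }
  out <- NULL
  for (stem in min_stem:max_stem) for (loop in loop_min:loop_max) {
    span <- 2 * stem + loop
    if (span > n) next
    for (i in 0:(n - span)) {
      cls <- character(stem)
      for (k in 1:stem) {
        cls[k] <- pairs(s[i + k], s[i + span + 1 - k])
      }
      mm <- sum(cls == "mm")
      if (mm > max_mismatch) next
      score <- 2 * sum(cls == "gc") + sum(cls %in% c("at", "gu")) -
        3 * mm - 0.1 * loop
      out <- rbind(out, data.frame(start = i, stem_len = stem,
                                   loop_len = loop, score = score))
    }
  }
  out
}

# Step-by-step TMM oracle using sort-based trimming (the package uses
# rank-based trimming; both must agree).
oracle_tmm <- function(obs, ref) {
  nO <- sum(obs); nR <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / nO) / (r / nR))
  A <- (log2(o / nO) + log2(r / nR)) / 2
  v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

# GeTMM oracle: recompute from first principles given the TMM factors.
oracle_getmm <- function(counts, lengths) {
  rpk <- counts / (lengths / 1000)
  f <- phagetu::tmm_factors(rpk)
  out <- rpk
  for (j in seq_len(ncol(rpk))) {
    out[, j] <- rpk[, j] / (sum(rpk[, j]) * f[j]) * 1e6
  }
  out
}

# Cumulative-minimum BH oracle.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Small standard simulation used by several tests.
small_dataset <- function(seed = 301L, n_tus = 6L, ...) {
  p <- sim_params(genome_length = 30000L, ...)
  arch <- generate_architecture(n_tus, p, seed = seed)
  genome <- plant_sequence(arch, p, seed = seed + 1L)
  tracks <- simulate_coverage(arch, p, seed = seed + 2L)
  list(params = p, arch = arch, genome = genome, tracks = tracks)
}
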