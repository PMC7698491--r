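# Synthetic genomes, regulatory architectures, stranded multi-timepoint
# coverage and ORF count matrices with the statistical structure the
# pipeline assumes, so every downstream stage is testable by recovery.
#
# Conventions: a TSS is stored as the genomic *boundary* index between the
# last untranscribed and first transcribed base (for a minus-strand unit
# the transcribed side is to the left of the boundary); a TTS is the
# boundary where coverage drops back. Local layouts are built in
# transcription coordinates and mirrored onto the plus strand for "-" units.

EARLY_M35 <- "TTGACW"
EARLY_EXT <- "TRTGN"
EARLY_M10 <- "TATANT"
LATE_CORE <- "TGTTATATTA"
LATE_UP <- "TWN"
LATE_DOWN <- "TT"

#' Simulation parameters
#'
#' Defaults emulate a lytic staphylococcal phage time course: an AT-rich
#' genome sampled at three timepoints (5, 15 and 30 min post-infection),
#' negative-binomial coverage noise, and progressive 5'-sided transcript
#' depletion at the later timepoints.
#'
#' @param genome_length Genome length in bp.
#' @param timepoints Timepoint labels, ordered; the last one is the late
#'   phase in which late promoters switch on.
#' @param dispersion Negative-binomial dispersion of per-base depth and of
#'   ORF counts (0 switches noise off and returns exact expectations).
#' @param degradation_rate Per-kb 5'-depletion coefficient; a promoter's
#'   contribution is damped by `exp(-rate * age * d3/1000)` where `age`
#'   counts timepoints since the promoter became active and `d3` is the
#'   distance to its closing terminator, so older transcripts are eroded
#'   from their 5' ends while freshly made late transcripts are not.
#' @param readthrough_decay Processivity length (bp) of transcripts that
#'   read through a terminator: the leaked contribution decays as
#'   `exp(-d/readthrough_decay)` past the terminator, keeping readthrough
#'   local instead of running out along the genome.
#' @param gc Background GC fraction of the simulated genome.
#' @param mutation_rate Per-position probability that a planted promoter
#'   box letter is replaced by a random different base.
#' @param read_scale Base pairs of depth contributing one read count.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 50000L,
                       timepoints = c("t5", "t15", "t30"),
                       dispersion = 0.1,
                       degradation_rate = 0.2,
                       readthrough_decay = 300,
                       gc = 0.35,
                       mutation_rate = 0.02,
                       read_scale = 100) {
  stopifnot(genome_length >= 1000, length(timepoints) >= 2,
            dispersion >= 0, degradation_rate >= 0, readthrough_decay > 0,
            gc > 0, gc < 1, mutation_rate >= 0, mutation_rate < 1)
  structure(
    list(genome_length = as.integer(genome_length),
         timepoints = as.character(timepoints),
         dispersion = dispersion, degradation_rate = degradation_rate,
         readthrough_decay = readthrough_decay,
         gc = gc, mutation_rate = mutation_rate, read_scale = read_scale),
    class = "sim_params"
  )
}

# Draw an early-promoter spacer (distance -35 3' end to -10 5' start).
draw_spacer <- function(n) {
  sample(c(16L, 17L, 18L), n, replace = TRUE, prob = c(0.05, 0.9, 0.05))
}

#' Generate a planted regulatory architecture
#'
#' Lays out `n_tus` non-overlapping transcription units on both strands,
#' each with a primary promoter, optional internal promoters, 1 to
#' `max_orfs` ORFs and a closing terminator, plus `n_regions` highly
#' expressed non-coding (lncRNA-like) regions with their own promoter and
#' terminator but no ORFs. Temporal classes are drawn from
#' `class_fractions`.
#'
#' @param n_tus Number of transcription units (>= 1).
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the same seed reproduces the architecture
#'   exactly.
#' @param class_fractions Named probabilities for TU classes
#'   `early`/`late`/`both`.
#' @param plus_fraction Probability that a unit lies on the plus strand.
#' @param max_orfs Maximum ORFs per TU.
#' @param n_regions Number of non-coding regions.
#' @return A list of class `phage_architecture` with data.frames
#'   `promoters`, `terminators`, `orfs`, `tus`, `regions`.
#' @export
generate_architecture <- function(n_tus, params = sim_params(), seed = 1L,
                                  class_fractions = c(early = 26, late = 4, both = 5) / 35,
                                  plus_fraction = 20 / 35,
                                  max_orfs = 6L,
                                  n_regions = 2L) {
  stopifnot(n_tus >= 1)
  class_fractions <- class_fractions / sum(class_fractions)
  with_seed(seed, {
    units <- vector("list", n_tus + n_regions)
    classes <- sample(names(class_fractions), n_tus, replace = TRUE,
                      prob = class_fractions)
    if (n_tus >= 3) {
      # guarantee at least one unit of each represented class at small n
      classes[seq_len(min(3, n_tus))] <- c("early", "late", "both")[seq_len(min(3, n_tus))]
      classes <- sample(classes)
    }
    for (i in seq_len(n_tus)) {
      units[[i]] <- layout_tu(sprintf("TU%02d", i), classes[i], max_orfs)
    }
    for (j in seq_len(n_regions)) {
      units[[n_tus + j]] <- layout_region(sprintf("lncRNA%d", j),
                                          if (j %% 2 == 1) "early" else "late")
    }
    # place units left to right with random intergenic gaps
    margin <- 40L
    widths <- vapply(units, function(u) as.integer(u$body_len) + 2L * margin,
                     integer(1))
    gaps <- sample(120:320, length(units), replace = TRUE)
    need <- sum(widths) + sum(gaps) + 200L
    if (need > params$genome_length) {
      stop("genome too short: need >= ", need, " bp for ", n_tus,
           " TUs and ", n_regions, " regions")
    }
    extra <- params$genome_length - need + 200L
    # spread the slack across the gaps
    bump <- diff(c(0, sort(sample(0:extra, length(units), replace = TRUE))))
    pos <- 100L
    prom <- list(); term <- list(); orf <- list(); tu <- list(); reg <- list()
    for (k in seq_along(units)) {
      u <- units[[k]]
      strand <- if (runif(1) < plus_fraction) "+" else "-"
      s0 <- pos
      s1 <- s0 + widths[k]
      # map local transcription boundary -> global boundary
      g <- if (strand == "+") function(x) s0 + margin + x else function(x) s1 - margin - x
      p <- u$promoters
      p$strand <- strand
      p$tss <- vapply(p$tss_local, g, numeric(1))
      tm <- u$terminators
      tm$strand <- strand
      tm$pos <- vapply(tm$pos_local, g, numeric(1))
      if (nrow(u$orfs) > 0) {
        o <- u$orfs
        o$strand <- strand
        gs <- vapply(o$start_local, g, numeric(1))
        ge <- vapply(o$end_local, g, numeric(1))
        o$start <- pmin(gs, ge)
        o$end <- pmax(gs, ge)
        orf[[length(orf) + 1L]] <- o[, c("id", "tu", "strand", "start", "end")]
      }
      span <- sort(c(g(0), g(u$body_len)))
      row <- data.frame(id = u$id, strand = strand, class = u$class,
                        start = span[1], end = span[2],
                        n_orfs = nrow(u$orfs), stringsAsFactors = FALSE)
      if (u$kind == "tu") tu[[length(tu) + 1L]] <- row else reg[[length(reg) + 1L]] <- row
      prom[[length(prom) + 1L]] <- p[, c("id", "tu", "class", "strand", "tss",
                                         "strength", "spacer")]
      term[[length(term) + 1L]] <- tm[, c("id", "tu", "strand", "pos", "stem_len",
                                         "loop_len", "gc_frac", "polyT_len",
                                         "readthrough")]
      pos <- s1 + gaps[k] + bump[k]
    }
    arch <- structure(
      list(promoters = do.call(rbind, prom),
           terminators = do.call(rbind, term),
           orfs = do.call(rbind, orf),
           tus = do.call(rbind, tu),
           regions = if (length(reg)) do.call(rbind, reg) else
             data.frame(id = character(), strand = character(),
                        class = character(), start = numeric(),
                        end = numeric(), n_orfs = integer()),
           genome_length = params$genome_length,
           timepoints = params$timepoints),
      class = "phage_architecture"
    )
    rownames(arch$promoters) <- NULL
    rownames(arch$terminators) <- NULL
    if (!is.null(arch$orfs)) rownames(arch$orfs) <- NULL
    arch
  })
}

# Lay out one TU in local transcription coordinates (0 = primary TSS
# boundary, increasing 5'->3').
layout_tu <- function(id, class, max_orfs) {
  n_orfs <- sample.int(max_orfs, 1L)
  orf_len <- sample(200:800, n_orfs, replace = TRUE)
  gap <- sample(20:60, n_orfs, replace = TRUE)
  start <- cumsum(c(30L, head(orf_len + gap, -1L)))
  end <- start + orf_len
  orfs <- data.frame(id = paste0(id, "_orf", seq_len(n_orfs)), tu = id,
                     start_local = start, end_local = end,
                     stringsAsFactors = FALSE)
  primary_class <- if (class == "late") "late" else "early"
  proms <- data.frame(id = paste0("p_", id, "_1"), tu = id,
                      class = primary_class, tss_local = 0,
                      strength = prom_strength(primary_class),
                      spacer = if (primary_class == "early") draw_spacer(1) else NA_integer_,
                      stringsAsFactors = FALSE)
  free_orfs <- if (n_orfs >= 2) 2:n_orfs else integer(0)
  if (class == "both") {
    tss <- if (length(free_orfs)) {
      k <- free_orfs[sample.int(length(free_orfs), 1L)]
      free_orfs <- setdiff(free_orfs, k)
      start[k] - 25
    } else 25
    proms <- rbind(proms, data.frame(
      id = paste0("pL_", id), tu = id, class = "late", tss_local = tss,
      strength = prom_strength("late"), spacer = NA_integer_))
  }
  if (primary_class == "early" && length(free_orfs) && runif(1) < 0.35) {
    k <- free_orfs[sample.int(length(free_orfs), 1L)]
    proms <- rbind(proms, data.frame(
      id = paste0("p_", id, "_int"), tu = id, class = "early",
      tss_local = start[k] - 25, strength = prom_strength("early"),
      spacer = draw_spacer(1)))
  }
  stem <- sample(6:12, 1L)
  loop <- sample(3:8, 1L)
  polyT <- sample(5:8, 1L)
  tts <- end[n_orfs] + 25 + 2 * stem + loop + 1 + polyT
  terms <- data.frame(id = paste0("t_", id), tu = id, pos_local = tts,
                      stem_len = stem, loop_len = loop,
                      gc_frac = runif(1, 0.7, 0.9), polyT_len = polyT,
                      readthrough = runif(1, 0.02, 0.25),
                      stringsAsFactors = FALSE)
  list(id = id, kind = "tu", class = class, body_len = tts,
       promoters = proms, terminators = terms, orfs = orfs)
}

# Non-coding highly expressed region: promoter + terminator, no ORFs.
layout_region <- function(id, class) {
  span <- sample(400:600, 1L)
  stem <- sample(7:11, 1L); loop <- sample(4:8, 1L); polyT <- sample(6:8, 1L)
  tts <- span + 2 * stem + loop + 1 + polyT
  proms <- data.frame(id = paste0("p_", id), tu = id, class = class,
                      tss_local = 0,
                      strength = runif(1, 500, 1200),
                      spacer = if (class == "early") draw_spacer(1) else NA_integer_,
                      stringsAsFactors = FALSE)
  terms <- data.frame(id = paste0("t_", id), tu = id, pos_local = tts,
                      stem_len = stem, loop_len = loop,
                      gc_frac = runif(1, 0.7, 0.9), polyT_len = polyT,
                      readthrough = runif(1, 0.02, 0.15),
                      stringsAsFactors = FALSE)
  list(id = id, kind = "region", class = class, body_len = tts,
       promoters = proms, terminators = terms,
       orfs = data.frame(id = character(), tu = character(),
                         start_local = numeric(), end_local = numeric()))
}

prom_strength <- function(class) {
  if (class == "early") exp(runif(1, log(60), log(350)))
  else exp(runif(1, log(250), log(700)))
}

# Promoter cassette in local transcription coordinates relative to the TSS
# boundary T: returns the payload string, its local interval [T-len, T) and
# a logical mask of consensus-box positions (eligible for mutation).
promoter_cassette <- function(class, spacer) {
  if (class == "early") {
    m35 <- sample_iupac(EARLY_M35)
    ext <- sample_iupac(EARLY_EXT)
    m10 <- sample_iupac(EARLY_M10)
    pad <- random_dna(spacer - 5L)
    gap <- random_dna(5L)
    payload <- paste0(m35, pad, ext, m10, gap)
    mask <- c(rep(TRUE, 6), rep(FALSE, spacer - 5L), rep(TRUE, 11), rep(FALSE, 5))
  } else {
    up <- sample_iupac(LATE_UP)
    core <- sample_iupac(LATE_CORE)
    # the downstream TT extension is an enrichment, not an invariant:
    # planting it literally would leave the core's alignment phase
    # degenerate over a 12 nt conserved run
    down <- paste(ifelse(runif(2L) < 0.85, "T",
                         sample(c("A", "C", "G"), 2L, replace = TRUE)),
                  collapse = "")
    gap <- random_dna(3L)
    payload <- paste0(up, core, down, gap)
    mask <- c(rep(TRUE, 13), rep(FALSE, 5))
  }
  list(payload = payload, len = nchar(payload), mask = mask)
}

# Terminator payload ending exactly at the TTS boundary. The stem
# realizes its gc_frac exactly (a composition, not a sampling rate), so
# every planted hairpin scores as its architecture row promises.
terminator_cassette <- function(stem_len, loop_len, gc_frac, polyT_len) {
  n_gc <- round(stem_len * gc_frac)
  stem1 <- paste(sample(c(sample(c("G", "C"), n_gc, replace = TRUE),
                          sample(c("A", "T"), stem_len - n_gc, replace = TRUE))),
                 collapse = "")
  loop <- random_dna(loop_len, gc = 0.4)
  payload <- paste0(stem1, loop, reverse_complement(stem1),
                    random_dna(1L, gc = 0.3), strrep("T", polyT_len))
  list(payload = payload, len = nchar(payload))
}

#' Plant a regulatory architecture into a genome sequence
#'
#' Writes every promoter cassette (boxes sampled from their IUPAC
#' consensus, optionally mutated) and every terminator hairpin + polyT
#' tract at its architecture coordinates, strand-aware: minus-strand
#' elements appear as the reverse complement on the plus-strand text.
#'
#' @param architecture A `phage_architecture`.
#' @param params A [sim_params()] object (background GC, mutation rate).
#' @param seed Integer seed.
#' @param background Optional background genome sequence of the right
#'   length; by default a random sequence at `params$gc` is drawn.
#' @return A [genome_record()] carrying the planted genome.
#' @export
plant_sequence <- function(architecture, params = sim_params(), seed = 1L,
                           background = NULL) {
  L <- architecture$genome_length
  with_seed(seed, {
    seq <- if (is.null(background)) random_dna(L, params$gc) else toupper(background)
    if (nchar(seq) != L) stop("background length != architecture genome_length")
    planted <- list()  # occupied intervals, for the overlap check
    write_payload <- function(gstart, gend, payload, strand) {
      for (iv in planted) {
        if (gstart < iv[2] && iv[1] < gend) {
          stop("overlapping planted elements at [", gstart, ",", gend, ")")
        }
      }
      planted[[length(planted) + 1L]] <<- c(gstart, gend)
      if (strand == "-") payload <- reverse_complement(payload)
      subseq0(seq, gstart, gend) <<- payload
    }
    pr <- architecture$promoters
    for (i in seq_len(nrow(pr))) {
      cas <- promoter_cassette(pr$class[i], pr$spacer[i])
      payload <- mutate_masked(cas$payload, cas$mask, params$mutation_rate)
      # cassette occupies [T-len, T) in transcription coordinates
      if (pr$strand[i] == "+") {
        write_payload(pr$tss[i] - cas$len, pr$tss[i], payload, "+")
      } else {
        write_payload(pr$tss[i], pr$tss[i] + cas$len, payload, "-")
      }
    }
    tr <- architecture$terminators
    for (i in seq_len(nrow(tr))) {
      cas <- terminator_cassette(tr$stem_len[i], tr$loop_len[i],
                                 tr$gc_frac[i], tr$polyT_len[i])
      if (tr$strand[i] == "+") {
        write_payload(tr$pos[i] - cas$len, tr$pos[i], cas$payload, "+")
      } else {
        write_payload(tr$pos[i], tr$pos[i] + cas$len, cas$payload, "-")
      }
    }
    genome_record("synthetic_phage", seq)
  })
}

mutate_masked <- function(payload, mask, rate) {
  if (rate <= 0) return(payload)
  ch <- strsplit(payload, "", fixed = TRUE)[[1]]
  hit <- which(mask & runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

# Promoter strength at each timepoint: early promoters are constitutive,
# late promoters fire only in the last (late) timepoint.
strength_profile <- function(class, strength, n_tp) {
  if (class == "early") rep(strength, n_tp)
  else c(rep(0, n_tp - 1L), strength)
}

# Noiseless expected depth per strand and timepoint. Each promoter
# contributes its strength from its TSS to its closing terminator (the
# first downstream terminator with readthrough < 0.5), damped by the
# 5'-depletion factor exp(-rate * age * d3/1000) where `age` counts the
# timepoints since the promoter became active (late transcripts are
# fresh at the last timepoint) and d3 is the distance to the closing
# terminator. Past each terminator the surviving fraction `readthrough`
# continues and decays with the processivity length
# `readthrough_decay`, so leakage does not run the genome out.
expected_coverage <- function(architecture, params) {
  L <- architecture$genome_length
  tps <- architecture$timepoints
  n_tp <- length(tps)
  lambda <- params$readthrough_decay
  out <- list()
  for (strand in c("+", "-")) {
    pr <- architecture$promoters[architecture$promoters$strand == strand, , drop = FALSE]
    tr <- architecture$terminators[architecture$terminators$strand == strand, , drop = FALSE]
    # terminators in transcription order
    tord <- if (nrow(tr)) order(tr$pos, decreasing = (strand == "-")) else integer(0)
    tpos <- tr$pos[tord]; trt <- tr$readthrough[tord]
    contribs <- vector("list", nrow(pr))
    for (i in seq_len(nrow(pr))) {
      contribs[[i]] <- promoter_contribution(
        pr$tss[i], strand, tpos, trt, L, lambda)
    }
    for (ti in seq_len(n_tp)) {
      E <- numeric(L)
      for (i in seq_len(nrow(pr))) {
        first_active <- if (pr$class[i] == "early") 1L else n_tp
        if (ti < first_active) next
        k <- params$degradation_rate * (ti - first_active)
        ctb <- contribs[[i]]
        prof <- ctb$profile
        if (k > 0 && length(ctb$deg_idx)) {
          prof[ctb$deg_idx] <- prof[ctb$deg_idx] * exp(-k * ctb$d3 / 1000)
        }
        E[ctb$idx] <- E[ctb$idx] + pr$strength[i] * prof
      }
      out[[paste(strand, tps[ti], sep = ".")]] <- E
    }
  }
  out
}

# Unit-strength contribution profile of one promoter: indices (1-based)
# of covered bases, relative depth there, and for bases upstream of the
# closing terminator the distance to it (degradation applies only to
# transcripts that end there; readthrough tails carry fresh 3' ends).
promoter_contribution <- function(tss, strand, tpos, trt, L, lambda) {
  dirn <- if (strand == "+") 1L else -1L
  downstream <- if (strand == "+") tpos > tss else tpos < tss
  tpos <- tpos[downstream]; trt <- trt[downstream]
  close_i <- which(trt < 0.5)[1]
  idx <- integer(0); profile <- numeric(0)
  deg_end <- NA_real_
  level <- 1
  cur <- tss
  seg <- function(a, b) {   # transcription-sense boundary interval [a, b)
    if (strand == "+") seq.int(a + 1L, b) else seq.int(b + 1L, a)
  }
  j <- 1L
  last_term <- NA_real_
  while (level > 1e-4) {
    nxt <- if (j <= length(tpos)) tpos[j] else if (strand == "+") L else 0L
    if ((strand == "+" && nxt > cur) || (strand == "-" && nxt < cur)) {
      b <- seg(cur, nxt)
      p <- if (is.na(last_term)) rep(level, length(b)) else {
        d <- abs((b - 0.5) - last_term)
        level * exp(-d / lambda)
      }
      idx <- c(idx, b); profile <- c(profile, p)
      if (!is.na(last_term)) level <- level * exp(-abs(nxt - last_term) / lambda)
    }
    if (j > length(tpos)) break
    if (!is.na(close_i) && j == close_i && is.na(deg_end)) deg_end <- tpos[j]
    level <- level * trt[j]
    last_term <- tpos[j]
    cur <- tpos[j]
    j <- j + 1L
  }
  if (is.na(deg_end)) deg_end <- if (strand == "+") L else 0L
  # degradation reference: bases between the TSS and the closing terminator
  deg_mask <- if (strand == "+") {
    idx > tss & idx <= deg_end
  } else {
    idx <= tss & idx > deg_end
  }
  d3 <- abs(deg_end - (idx[deg_mask] - ifelse(strand == "+", 0, 1)))
  list(idx = idx, profile = profile, deg_idx = which(deg_mask), d3 = d3)
}

#' Simulate strand-specific multi-timepoint coverage
#'
#' Expected depth follows the planted architecture (promoter strengths,
#' terminator readthrough, 5' depletion); per-base negative-binomial noise
#' is added unless `params$dispersion == 0`, in which case the exact
#' expectation is returned.
#'
#' @param architecture A `phage_architecture`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return Named list of [coverage_track()]s, one per strand x timepoint,
#'   names like `"t5.+"`.
#' @export
simulate_coverage <- function(architecture, params = sim_params(), seed = 1L) {
  E <- expected_coverage(architecture, params)
  with_seed(seed, {
    tracks <- list()
    for (nm in names(E)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      depth <- if (params$dispersion > 0) {
        mu <- E[[nm]]
        d <- numeric(length(mu))
        pos <- mu > 0
        d[pos] <- stats::rnbinom(sum(pos), size = 1 / params$dispersion, mu = mu[pos])
        d
      } else E[[nm]]
      tracks[[paste(parts[2], parts[1], sep = ".")]] <-
        coverage_track(depth, parts[1], parts[2])
    }
    tracks
  })
}

#' Simulate an ORF x (timepoint, replicate) count matrix
#'
#' Counts are negative-binomial draws with mean equal to the unit's mean
#' expected depth over the ORF times ORF length over `read_scale`.
#' Non-coding regions are quantified alongside ORFs as pseudo-genes.
#'
#' @param architecture A `phage_architecture`.
#' @param params A [sim_params()] object.
#' @param n_replicates Replicates per timepoint.
#' @param seed Integer seed.
#' @return A list of class `count_matrix`: integer matrix `counts`
#'   (features x samples), `lengths` (bp), `samples` data.frame with
#'   `timepoint` and `replicate`.
#' @export
simulate_counts <- function(architecture, params = sim_params(),
                            n_replicates = 3L, seed = 1L) {
  stopifnot(n_replicates >= 1)
  E <- expected_coverage(architecture, params)
  feats <- rbind(
    architecture$orfs[, c("id", "strand", "start", "end")],
    architecture$regions[, c("id", "strand", "start", "end")]
  )
  tps <- architecture$timepoints
  mu <- vapply(tps, function(tp) {
    vapply(seq_len(nrow(feats)), function(i) {
      e <- E[[paste(feats$strand[i], tp, sep = ".")]]
      mean(e[(feats$start[i] + 1L):feats$end[i]]) *
        (feats$end[i] - feats$start[i]) / params$read_scale
    }, numeric(1))
  }, numeric(nrow(feats)))
  mu <- matrix(mu, nrow = nrow(feats), dimnames = list(feats$id, tps))
  with_seed(seed, {
    samples <- expand.grid(replicate = seq_len(n_replicates), timepoint = tps,
                           stringsAsFactors = FALSE)[, 2:1]
    counts <- matrix(0L, nrow(feats), nrow(samples),
                     dimnames = list(feats$id, paste0(samples$timepoint, "_r",
                                                      samples$replicate)))
    for (s in seq_len(nrow(samples))) {
      # mild library-size jitter; off in the exact (dispersion 0) regime
      libfac <- if (params$dispersion > 0) exp(stats::rnorm(1, 0, 0.05)) else 1
      m <- mu[, samples$timepoint[s]] * libfac
      counts[, s] <- if (params$dispersion > 0) {
        stats::rnbinom(nrow(feats), size = 1 / params$dispersion, mu = m)
      } else as.integer(round(m))
    }
    structure(list(counts = counts,
                   lengths = stats::setNames(feats$end - feats$start, feats$id),
                   samples = samples),
              class = "count_matrix")
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [generate_architecture()],
#' [plant_sequence()], [simulate_coverage()] and [simulate_counts()] with
#' sub-seeds derived from `seed`.
#'
#' @inheritParams generate_architecture
#' @param n_replicates Replicates per timepoint for the count matrix.
#' @param ... Passed to [generate_architecture()].
#' @return List with `architecture`, `genome`, `tracks`, `counts`.
#' @export
simulate_dataset <- function(n_tus = 12L, params = sim_params(), seed = 1L,
                             n_replicates = 3L, ...) {
  seed <- as.integer(seed) %% 536870000L
  arch <- generate_architecture(n_tus, params, seed = seed, ...)
  genome <- plant_sequence(arch, params, seed = seed + 1L)
  tracks <- simulate_coverage(arch, params, seed = seed + 2L)
  counts <- simulate_counts(arch, params, n_replicates, seed = seed + 3L)
  list(architecture = arch, genome = genome, tracks = tracks, counts = counts)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, ORF GFF3, one bedGraph per strand and timepoint, a counts
#' TSV and truth tables (promoters, terminators, TUs) for scoring.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genome, file.path(dir, "genome.fasta"))
  write_gff(dataset$architecture$orfs[, c("id", "start", "end", "strand", "tu")],
            file.path(dir, "orfs.gff3"), seqname = dataset$genome$id)
  for (nm in names(dataset$tracks)) {
    tr <- dataset$tracks[[nm]]
    tr$seqname <- dataset$genome$id
    fn <- sprintf("coverage_%s_%s.bedgraph", tr$timepoint,
                  if (tr$strand == "+") "plus" else "minus")
    write_bedgraph(tr, file.path(dir, fn))
  }
  cm <- dataset$counts
  tab <- data.frame(id = rownames(cm$counts), length = cm$lengths, cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$architecture$promoters,
                     file.path(dir, "truth_promoters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$architecture$terminators,
                     file.path(dir, "truth_terminators.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$architecture$tus, file.path(dir, "truth_tus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
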