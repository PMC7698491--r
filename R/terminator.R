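# Rho-independent terminator calling at down-step windows: exhaustive
# stem-loop enumeration with an additive pairing score, a mandatory polyT
# tract, and coverage-based readthrough estimation.
#
# Thermodynamic folding is deliberately replaced by direct enumeration:
# the calling criterion is structural (GC-rich stem-loop followed by a
# polyT run), enumeration over all (start, stem, loop) triples is exact,
# and the additive score keeps every decision inspectable.

#' Terminator-calling parameters
#'
#' @param min_stem,max_stem Stem length range (bp).
#' @param loop_min,loop_max Loop length range (nt).
#' @param max_mismatch Maximum unpaired positions tolerated in the stem.
#' @param gu_pairs Treat G.T (RNA G.U) as a weak pair.
#' @param min_score Minimum hairpin score (2 per G:C pair, 1 per A:T or
#'   G.U pair, -3 per mismatch, -0.1 per loop nt).
#' @param min_T Minimum number of T's in the polyT tract.
#' @param max_gap Maximum distance (nt) from the stem 3' side to the
#'   start of the polyT tract.
#' @return A list of class `terminator_params`.
#' @export
terminator_params <- function(min_stem = 5L, max_stem = 15L, loop_min = 3L,
                              loop_max = 9L, max_mismatch = 1L,
                              gu_pairs = TRUE, min_score = 8,
                              min_T = 4L, max_gap = 3L) {
  stopifnot(min_stem >= 2, max_stem >= min_stem, loop_min >= 1,
            loop_max >= loop_min, max_mismatch >= 0, min_T >= 1, max_gap >= 0)
  structure(list(min_stem = as.integer(min_stem), max_stem = as.integer(max_stem),
                 loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
                 max_mismatch = as.integer(max_mismatch), gu_pairs = gu_pairs,
                 min_score = min_score, min_T = as.integer(min_T),
                 max_gap = as.integer(max_gap)),
            class = "terminator_params")
}

# Pair class of stem letters a (5' arm) and b (3' arm, read 5'->3'):
# "gc", "at", "gu" or "mm".
pair_class <- function(a, b, gu_pairs) {
  ifelse((a == "G" & b == "C") | (a == "C" & b == "G"), "gc",
    ifelse((a == "A" & b == "T") | (a == "T" & b == "A"), "at",
      ifelse(gu_pairs & ((a == "G" & b == "T") | (a == "T" & b == "G")),
             "gu", "mm")))
}

#' Enumerate hairpin candidates in a window
#'
#' All placements `(start, stem_len, loop_len)` within the parameter
#' ranges where the two stem arms reverse-complement pair with at most
#' `max_mismatch` mismatches are returned with their additive score.
#'
#' @param window_seq Sequence (transcription orientation).
#' @param params A [terminator_params()] object.
#' @return data.frame `start` (0-based within the window), `stem_len`,
#'   `loop_len`, `gc_pairs`, `weak_pairs`, `mismatches`, `gc_frac` (GC
#'   fraction of the 5' stem arm), `score`, `end3` (0-based position just
#'   past the 3' stem arm). A window too short for any placement yields
#'   zero rows.
#' @export
find_hairpins <- function(window_seq, params = terminator_params()) {
  s <- strsplit(toupper(window_seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  out <- list()
  for (stem in params$min_stem:params$max_stem) {
    for (loop in params$loop_min:params$loop_max) {
      span <- 2L * stem + loop
      if (span > n) next
      for (i in 0:(n - span)) {
        arm1 <- s[(i + 1L):(i + stem)]
        arm2 <- s[(i + stem + loop + 1L):(i + span)]
        cls <- pair_class(arm1, rev(arm2), params$gu_pairs)
        mm <- sum(cls == "mm")
        if (mm > params$max_mismatch) next
        gc <- sum(cls == "gc")
        weak <- sum(cls %in% c("at", "gu"))
        score <- 2 * gc + weak - 3 * mm - 0.1 * loop
        out[[length(out) + 1L]] <- data.frame(
          start = i, stem_len = stem, loop_len = loop, gc_pairs = gc,
          weak_pairs = weak, mismatches = mm,
          gc_frac = mean(arm1 %in% c("G", "C")), score = score,
          end3 = i + span
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), gc_pairs = integer(),
                      weak_pairs = integer(), mismatches = integer(),
                      gc_frac = numeric(), score = numeric(),
                      end3 = integer()))
  }
  res <- do.call(rbind, out)
  res[order(-res$score, res$start), , drop = FALSE]
}

# PolyT tract immediately downstream of a hairpin arm end: the number of
# T's in a run starting within `max_gap` nt, allowing one internal non-T.
polyt_run <- function(chars, from, params) {
  n <- length(chars)
  best <- 0L
  for (d in 0:params$max_gap) {
    j <- from + d + 1L
    if (j > n || chars[j] != "T") next
    tcount <- 0L; skips <- 0L; k <- j
    while (k <= n) {
      if (chars[k] == "T") {
        tcount <- tcount + 1L
      } else if (skips < 1L && k < n && chars[k + 1L] == "T") {
        skips <- skips + 1L
      } else break
      k <- k + 1L
    }
    best <- max(best, tcount)
  }
  best
}

#' Call a terminator in one down-step window
#'
#' The best-scoring hairpin whose score reaches `min_score` *and* that is
#' followed (within `max_gap` nt of its 3' arm) by a run of at least
#' `min_T` T's (one internal non-T tolerated) yields a call; a hairpin
#' without the tract, or a tract without the hairpin, does not.
#'
#' @param window_seq Window sequence in transcription orientation.
#' @param params A [terminator_params()] object.
#' @return One-row data.frame (`stem_len`, `loop_len`, `gc_frac`,
#'   `hairpin_score`, `polyT_len`, `hairpin_start`) or `NULL` when no
#'   placement qualifies.
#' @export
call_terminator <- function(window_seq, params = terminator_params()) {
  hp <- find_hairpins(window_seq, params)
  hp <- hp[hp$score >= params$min_score, , drop = FALSE]
  if (nrow(hp) == 0L) return(NULL)
  chars <- strsplit(toupper(window_seq), "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(hp))) {
    tlen <- polyt_run(chars, hp$end3[i], params)
    if (tlen >= params$min_T) {
      return(data.frame(stem_len = hp$stem_len[i], loop_len = hp$loop_len[i],
                        gc_frac = hp$gc_frac[i], hairpin_score = hp$score[i],
                        polyT_len = tlen, hairpin_start = hp$start[i]))
    }
  }
  NULL
}

#' Readthrough fraction at a terminator
#'
#' Mean depth just downstream of the terminator boundary divided by mean
#' depth just upstream, in transcription direction, clamped to `[0, 1]`.
#' Undefined (NA) when the upstream side is essentially uncovered.
#'
#' @param track A [coverage_track()] on the terminator's strand.
#' @param position Terminator boundary (0-based).
#' @param strand Terminator strand.
#' @param flank Flank width in bp on each side.
#' @param min_upstream Below this upstream mean depth the estimate is NA.
#' @return Readthrough in `[0, 1]`, or NA.
#' @export
readthrough_fraction <- function(track, position, strand = track$strand,
                                 flank = 100L, min_upstream = 1) {
  L <- length(track$depth)
  lo <- max(0L, position - flank)
  hi <- min(L, position + flank)
  left <- if (position > lo) mean(track$depth[(lo + 1L):position]) else 0
  right <- if (hi > position) mean(track$depth[(position + 1L):hi]) else 0
  up <- if (strand == "+") left else right
  down <- if (strand == "+") right else left
  if (up < min_upstream) return(NA_real_)
  min(max(down / up, 0), 1)
}

#' Call terminators at all down-steps of a landscape
#'
#' @param genome A [genome_record()].
#' @param timed_steps Steps from [classify_step_timing()].
#' @param tracks Named list of coverage tracks (`"<tp>.<strand>"`).
#' @param timepoints Ordered timepoint labels.
#' @param params A [terminator_params()] object.
#' @param halfwidth Down-step window half width.
#' @return data.frame of terminator calls with per-timepoint readthrough
#'   columns `rt_<tp>` and `readthrough` (last timepoint's value).
#' @export
call_terminators <- function(genome, timed_steps, tracks, timepoints,
                             params = terminator_params(), halfwidth = 50L) {
  wins <- extract_downstep_windows(genome, timed_steps, halfwidth)
  out <- list()
  for (i in seq_len(nrow(wins))) {
    call <- call_terminator(wins$sequence[i], params)
    if (is.null(call)) next
    row <- data.frame(position = wins$position[i], strand = wins$strand[i],
                      call, stringsAsFactors = FALSE)
    for (tp in timepoints) {
      trk <- tracks[[paste(tp, wins$strand[i], sep = ".")]]
      row[[paste0("rt_", tp)]] <- if (is.null(trk)) NA_real_ else
        readthrough_fraction(trk, wins$position[i], wins$strand[i])
    }
    row$readthrough <- row[[paste0("rt_", timepoints[length(timepoints)])]]
    out[[length(out) + 1L]] <- row
  }
  res <- if (length(out)) do.call(rbind, out) else {
    base <- data.frame(position = integer(), strand = character(),
                       stem_len = integer(), loop_len = integer(),
                       gc_frac = numeric(), hairpin_score = numeric(),
                       polyT_len = integer(), hairpin_start = integer())
    for (tp in timepoints) base[[paste0("rt_", tp)]] <- numeric(0)
    base$readthrough <- numeric(0)
    base
  }
  rownames(res) <- NULL
  res
}
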