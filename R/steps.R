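# TSS/TTS candidate detection as sharp up-/down-steps in strand-specific
# coverage, plus temporal classification and sequence-window extraction.
#
# A step "position" is the genomic boundary index p between bases p-1 and
# p. Direction (up = TSS-like, down = TTS-like) is in the transcription
# sense of the track's strand: on the minus strand a genomic fall in depth
# is an up-step.

#' Step-detection parameters
#'
#' The detector compares mean depth in `[p-w, p)` against `[p, p+w)` at
#' every boundary and keeps locally maximal fold changes.
#'
#' @param w Window half-width in bp (each side of the boundary).
#' @param min_fold Minimum (high+eps)/(low+eps) fold.
#' @param min_high_depth Minimum mean depth on the high side.
#' @param merge_distance Candidates closer than this are merged, keeping
#'   the max-fold one.
#' @param eps Pseudocount stabilising the fold ratio.
#' @return A list of class `step_params`.
#' @export
step_params <- function(w = 50L, min_fold = 2, min_high_depth = 10,
                        merge_distance = 25L, eps = 1) {
  stopifnot(w >= 1, min_fold > 1, min_high_depth >= 0,
            merge_distance >= 0, eps > 0)
  structure(list(w = as.integer(w), min_fold = min_fold,
                 min_high_depth = min_high_depth,
                 merge_distance = as.integer(merge_distance), eps = eps),
            class = "step_params")
}

#' Detect coverage steps in one track
#'
#' @param track A [coverage_track()].
#' @param params A [step_params()] object.
#' @return data.frame with columns `position` (boundary index), `direction`
#'   (`up`/`down`, transcription sense), `strand`, `fold`,
#'   `high_side_depth`, `timepoint`. Rows ordered by position.
#' @export
detect_steps <- function(track, params = step_params()) {
  w <- params$w
  depth <- track$depth
  L <- length(depth)
  if (2L * w > L) stop("window w = ", w, " too long for a ", L, " bp genome")
  cs <- cumsum(c(0, depth))
  p <- w:(L - w)                       # admissible boundary positions
  left <- (cs[p + 1L] - cs[p - w + 1L]) / w
  right <- (cs[p + w + 1L] - cs[p + 1L]) / w
  # window means are clamped at zero so that signed residual tracks
  # (late minus early baseline) can be scanned with the same machinery
  hi <- pmax(pmax(left, right), 0)
  lo <- pmax(pmin(left, right), 0)
  fold <- (hi + params$eps) / (lo + params$eps)
  rising <- right > left
  keep <- fold >= params$min_fold & hi >= params$min_high_depth & left != right
  if (!any(keep)) {
    return(empty_steps(track))
  }
  cand <- data.frame(
    position = p[keep],
    rising = rising[keep],
    fold = fold[keep],
    high_side_depth = hi[keep]
  )
  # greedy merge: strongest first, suppress same-direction neighbours.
  # The suppression radius is at least w: the two-window fold statistic
  # has support width w, so a strong boundary casts secondary
  # above-threshold candidates up to w-1 bp away that are not distinct
  # steps.
  radius <- max(params$merge_distance, w)
  cand <- cand[order(-cand$fold, cand$position), , drop = FALSE]
  kept <- logical(nrow(cand))
  for (dirn in c(TRUE, FALSE)) {
    idx <- which(cand$rising == dirn)
    taken <- numeric(0)
    for (i in idx) {
      if (!length(taken) ||
          min(abs(taken - cand$position[i])) >= radius) {
        kept[i] <- TRUE
        taken <- c(taken, cand$position[i])
      }
    }
  }
  cand <- cand[kept, , drop = FALSE]
  direction <- if (track$strand == "+") {
    ifelse(cand$rising, "up", "down")
  } else {
    ifelse(cand$rising, "down", "up")
  }
  out <- data.frame(
    position = cand$position, direction = direction, strand = track$strand,
    fold = cand$fold, high_side_depth = cand$high_side_depth,
    timepoint = track$timepoint, stringsAsFactors = FALSE
  )
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_steps <- function(track = NULL) {
  data.frame(position = integer(), direction = character(),
             strand = character(), fold = numeric(),
             high_side_depth = numeric(), timepoint = character(),
             stringsAsFactors = FALSE)
}

#' Detect steps across all tracks of an experiment
#'
#' @param tracks List of [coverage_track()]s (both strands, all
#'   timepoints).
#' @param params A [step_params()] object.
#' @return One data.frame of steps from all tracks.
#' @export
detect_steps_all <- function(tracks, params = step_params()) {
  out <- lapply(tracks, detect_steps, params = params)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign temporal classes to steps across timepoints
#'
#' Steps from all timepoints are clustered by strand, direction and
#' position (within `merge_distance`). A cluster is *early* when detected
#' at any of the first `n_early_tp` timepoints (the pooled early window)
#' and *late* when detected only at later timepoints. A position detected
#' both early and late stays early: transcription is ongoing.
#'
#' @param steps data.frame from [detect_steps_all()].
#' @param timepoints Ordered timepoint labels of the experiment.
#' @param n_early_tp How many leading timepoints form the pooled early
#'   window (default 2).
#' @param merge_distance Position tolerance for matching steps across
#'   timepoints.
#' @return data.frame with one row per clustered step: `position` (of the
#'   max-fold member), `direction`, `strand`, `fold`, `high_side_depth`,
#'   `timing` (`early`/`late`), `timepoints` (comma-joined labels).
#' @export
classify_step_timing <- function(steps, timepoints, n_early_tp = 2L,
                                 merge_distance = 25L) {
  if (nrow(steps) == 0L) {
    return(cbind(empty_steps(), data.frame(timing = character(),
                                           timepoints = character())))
  }
  early_set <- timepoints[seq_len(min(n_early_tp, length(timepoints)))]
  res <- list()
  for (strand in unique(steps$strand)) {
    for (dirn in unique(steps$direction)) {
      s <- steps[steps$strand == strand & steps$direction == dirn, , drop = FALSE]
      if (nrow(s) == 0L) next
      s <- s[order(s$position), , drop = FALSE]
      cluster <- cumsum(c(1L, diff(s$position) > merge_distance))
      for (cl in unique(cluster)) {
        m <- s[cluster == cl, , drop = FALSE]
        best <- m[which.max(m$fold), , drop = FALSE]
        tps <- sort(unique(m$timepoint))
        timing <- if (any(tps %in% early_set)) "early" else "late"
        best$timepoint <- NULL
        best$timing <- timing
        best$timepoints <- paste(intersect(timepoints, tps), collapse = ",")
        res[[length(res) + 1L]] <- best
      }
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract sequence windows upstream of up-steps
#'
#' Strand-aware: for a plus-strand step at boundary `p` the window is
#' plus-strand bases `[p-length, p)`; for a minus-strand step it is the
#' reverse complement of `[p, p+length)`, so the returned sequence always
#' reads 5' to 3' toward the TSS. Windows truncated at genome edges are
#' flagged.
#'
#' @param genome A [genome_record()].
#' @param steps data.frame of up-steps (rows with `direction == "up"` are
#'   used).
#' @param length Window length in bp.
#' @return data.frame `position`, `strand`, `sequence`, `truncated`.
#' @export
extract_upstream_windows <- function(genome, steps, length = 100L) {
  steps <- steps[steps$direction == "up", , drop = FALSE]
  L <- genome$length
  out <- lapply(seq_len(nrow(steps)), function(i) {
    p <- steps$position[i]
    if (steps$strand[i] == "+") {
      a <- max(0L, p - length); b <- p
      s <- subseq0(genome$sequence, a, b)
    } else {
      a <- p; b <- min(L, p + length)
      s <- reverse_complement(subseq0(genome$sequence, a, b))
    }
    data.frame(position = p, strand = steps$strand[i], sequence = s,
               truncated = (b - a) < length, stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), strand = character(),
               sequence = character(), truncated = logical())
  rownames(res) <- NULL
  res
}

#' Extract sequence windows centered on down-steps
#'
#' The window covers `halfwidth` bp on each side of the boundary and is
#' oriented in the transcription direction (reverse complemented for
#' minus-strand steps), so the transcribed upstream side comes first.
#'
#' @param genome A [genome_record()].
#' @param steps data.frame of down-steps (rows with `direction == "down"`).
#' @param halfwidth Half window width in bp.
#' @return data.frame `position`, `strand`, `sequence`, `truncated`,
#'   `offset` (genomic start of the window on the plus strand).
#' @export
extract_downstep_windows <- function(genome, steps, halfwidth = 50L) {
  steps <- steps[steps$direction == "down", , drop = FALSE]
  L <- genome$length
  out <- lapply(seq_len(nrow(steps)), function(i) {
    p <- steps$position[i]
    a <- max(0L, p - halfwidth); b <- min(L, p + halfwidth)
    s <- subseq0(genome$sequence, a, b)
    if (steps$strand[i] == "-") s <- reverse_complement(s)
    data.frame(position = p, strand = steps$strand[i], sequence = s,
               truncated = (b - a) < 2L * halfwidth, offset = a,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), strand = character(),
               sequence = character(), truncated = logical(),
               offset = integer())
  rownames(res) <- NULL
  res
}
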