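# The two-box early promoter model (TTGACW -35, 16-18 bp spacer with the
# TRTGN extension occupying its last 5 nt, TATANT -10), genome-wide
# scanning for both promoter classes, and temporal classification of
# calls against coverage steps.

#' Construct an early promoter model from its two PWMs
#'
#' Total score of a placement is `score(-35) + score(ext+-10 block) -
#' spacer_penalty(spacer)` where the spacer is the distance from the -35
#' 3' end to the -10 5' start and the 11-column block covers TRTGN+TATANT
#' (the extension fills the last 5 spacer positions).
#'
#' @param pwm_35 Width-6 `pwm_model` of the -35 box.
#' @param pwm_10ext Width-11 `pwm_model` of the ext + -10 block.
#' @param spacers Allowed spacer lengths.
#' @param spacer_penalty Score penalty (bits) per spacer, same order as
#'   `spacers`; the common 17 bp spacer carries none.
#' @param threshold Training-recovery score threshold (may be set later).
#' @return An object of class `early_promoter_model`.
#' @export
early_promoter_model <- function(pwm_35, pwm_10ext,
                                 spacers = c(16L, 17L, 18L),
                                 spacer_penalty = c(1.5, 0, 1.5),
                                 threshold = NA_real_) {
  stopifnot(pwm_35$width == 6L, pwm_10ext$width == 11L,
            length(spacers) == length(spacer_penalty))
  structure(
    list(pwm_35 = pwm_35, pwm_10ext = pwm_10ext, spacers = as.integer(spacers),
         spacer_penalty = spacer_penalty, threshold = threshold,
         tss_offset = 5L),
    class = "early_promoter_model"
  )
}

#' @export
print.early_promoter_model <- function(x, ...) {
  cat("<early_promoter_model> -35", consensus_iupac(x$pwm_35),
      "| ext+-10", consensus_iupac(x$pwm_10ext),
      "| spacers", paste(x$spacers, collapse = "/"),
      "| threshold", signif(x$threshold, 4), "\n")
  invisible(x)
}

# Score an early-model placement inside a window: the block's 0-based
# offset within the window determines the -35 position per spacer.
# Returns best total score and the spacer achieving it.
score_early_placement <- function(model, window, block_offset) {
  block <- substr(window, block_offset + 1L, block_offset + 11L)
  s10 <- pwm_score(model$pwm_10ext, block)
  best <- -Inf; best_s <- NA_integer_
  for (k in seq_along(model$spacers)) {
    s <- model$spacers[k]
    a35 <- block_offset - (s - 5L) - 6L
    if (a35 < 0L) next
    s35 <- pwm_score(model$pwm_35, substr(window, a35 + 1L, a35 + 6L))
    tot <- s10 + s35 - model$spacer_penalty[k]
    if (tot > best) { best <- tot; best_s <- s }
  }
  list(score = best, spacer = best_s)
}

#' Scan a genome with a promoter model
#'
#' Both strands are scanned at every position; hits with score at or
#' above `threshold` are reported, same-strand hits within `collapse` bp
#' collapsed to the best score (ties to the leftmost). The TSS is placed
#' 6 bp downstream of the -10 box 3' end. Coordinates are 0-based; the
#' `tss` column is the boundary index of the first transcribed base in
#' transcription direction, the `box10_start`/`box10_end` columns the
#' plus-strand interval of the -10 box (last 6 columns of the block for
#' the early model, last 6 of the late core otherwise).
#'
#' @param model A `pwm_model` or `early_promoter_model`.
#' @param genome A [genome_record()].
#' @param threshold Score cutoff; defaults to the model's
#'   training-recovery threshold.
#' @param collapse Same-strand merge distance in bp.
#' @return data.frame of promoter calls: `tss`, `strand`, `score`,
#'   `spacer`, `box10_start`, `box10_end`, `source`.
#' @export
scan_genome <- function(model, genome, threshold = model$threshold,
                        collapse = 5L) {
  UseMethod("scan_genome")
}

#' @export
scan_genome.pwm_model <- function(model, genome, threshold = model$threshold,
                                  collapse = 5L) {
  if (is.na(threshold)) stop("no threshold: set one or use training_threshold()")
  scan_two_strands(genome, collapse, function(x) {
    s <- score_positions(model$logodds, x)
    list(score = s, spacer = rep(NA_integer_, length(s)), width = model$width)
  }, threshold, model$width, model$tss_offset)
}

#' @export
scan_genome.early_promoter_model <- function(model, genome,
                                             threshold = model$threshold,
                                             collapse = 5L) {
  if (is.na(threshold)) stop("no threshold: set one or use training_threshold()")
  scan_two_strands(genome, collapse, function(x) {
    s10 <- score_positions(model$pwm_10ext$logodds, x)   # indexed by block start
    s35 <- score_positions(model$pwm_35$logodds, x)
    n <- length(s10)
    best <- rep(-Inf, n); spacer <- rep(NA_integer_, n)
    for (k in seq_along(model$spacers)) {
      sp <- model$spacers[k]
      off <- sp - 5L + 6L                      # block start minus -35 start
      idx <- seq_len(n)
      i35 <- idx - off
      ok <- i35 >= 1L
      tot <- rep(-Inf, n)
      tot[ok] <- s10[ok] + s35[i35[ok]] - model$spacer_penalty[k]
      upd <- tot > best
      best[upd] <- tot[upd]
      spacer[upd] <- sp
    }
    list(score = best, spacer = spacer, width = 11L)
  }, threshold, 11L, model$tss_offset)
}

# Shared scanning core: scorer(x) returns scores indexed by the 0-based
# start of the -10-bearing block on the scanned strand text.
scan_two_strands <- function(genome, collapse, scorer, threshold, width,
                             tss_offset) {
  L <- genome$length
  res <- list()
  for (strand in c("+", "-")) {
    seqtxt <- if (strand == "+") genome$sequence else
      reverse_complement(genome$sequence)
    sc <- scorer(seq_to_int(seqtxt))
    # tiny guard so accumulated rounding can never drop a site scoring
    # exactly at the threshold
    hit <- which(sc$score >= threshold - 1e-9)
    if (!length(hit)) next
    df <- data.frame(start_local = hit - 1L, score = sc$score[hit],
                     spacer = sc$spacer[hit])
    # collapse same-strand hits within `collapse` bp, best score wins,
    # ties to the leftmost
    df <- df[order(-df$score, df$start_local), , drop = FALSE]
    taken <- integer(0); keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!length(taken) || min(abs(taken - df$start_local[i])) > collapse) {
        keep[i] <- TRUE
        taken <- c(taken, df$start_local[i])
      }
    }
    df <- df[keep, , drop = FALSE]
    block_end_local <- df$start_local + width      # 3' end of -10 box
    tss_local <- block_end_local + tss_offset
    if (strand == "+") {
      tss <- tss_local
      b10 <- cbind(block_end_local - 6L, block_end_local)
    } else {
      tss <- L - tss_local
      b10 <- cbind(L - block_end_local, L - block_end_local + 6L)
    }
    res[[strand]] <- data.frame(
      tss = tss, strand = strand, score = df$score, spacer = df$spacer,
      box10_start = b10[, 1], box10_end = b10[, 2],
      source = "pwm", stringsAsFactors = FALSE
    )
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(tss = integer(), strand = character(), score = numeric(),
               spacer = integer(), box10_start = integer(),
               box10_end = integer(), source = character())
  out <- out[order(out$tss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the early promoter model from training windows
#'
#' Stage 1 discovers the 11-column ext + -10 block by ZOOPS EM; stage 2
#' aligns the -35 hexamer upstream of each located block across the
#' allowed spacers, iterating the spacer choice against the evolving -35
#' PWM. The model threshold is the minimum total training-site score.
#'
#' @param windows Character vector of 100 bp upstream windows (read 5'
#'   to 3' toward the TSS).
#' @param seed Integer seed for motif discovery.
#' @param n_restarts EM restarts for the block search.
#' @return An `early_promoter_model` with fields `sites` (training
#'   placements: `window`, `block_offset`, `spacer`, `score`) and
#'   `consensus` (list with `m35`, `ext`, `m10`).
#' @export
build_early_model <- function(windows, seed = 1L, n_restarts = 20L) {
  block_pwm <- discover_motif(windows, width = 11L, n_restarts = n_restarts,
                              seed = seed)
  sites <- block_pwm$sites
  bg <- block_pwm$background
  spacers <- c(16L, 17L, 18L)
  penalty <- c(1.5, 0, 1.5)
  # initial -35 alignment at the canonical 17 bp spacer
  get35 <- function(w, block_off, s) {
    a <- block_off - (s - 5L) - 6L
    if (a < 0L) return(NA_character_)
    substr(windows[w], a + 1L, a + 6L)
  }
  cur <- mapply(get35, sites$window, sites$offset,
                MoreArgs = list(s = 17L))
  chosen <- rep(17L, nrow(sites))
  keep <- !is.na(cur)
  if (sum(keep) < 2L) stop("training blocks sit too close to the window edge")
  pwm35 <- build_pwm(cur[keep], pseudocount = 1, background = bg)
  for (it in 1:4) {
    for (i in seq_len(nrow(sites))) {
      best <- -Inf
      for (k in seq_along(spacers)) {
        cand <- get35(sites$window[i], sites$offset[i], spacers[k])
        if (is.na(cand)) next
        sc <- pwm_score(pwm35, cand) - penalty[k]
        if (sc > best) { best <- sc; chosen[i] <- spacers[k] }
      }
    }
    cur <- mapply(get35, sites$window, sites$offset, chosen)
    keep <- !is.na(cur)
    pwm35 <- build_pwm(cur[keep], pseudocount = 1, background = bg)
  }
  model <- early_promoter_model(pwm35, block_pwm)
  scores <- vapply(which(keep), function(i) {
    score_early_placement(model, windows[sites$window[i]], sites$offset[i])$score
  }, numeric(1))
  model$threshold <- min(scores)
  model$sites <- data.frame(window = sites$window[keep],
                            block_offset = sites$offset[keep],
                            spacer = chosen[keep], score = scores)
  model$consensus <- list(
    m35 = consensus_iupac(pwm35),
    ext = substr(consensus_iupac(block_pwm), 1, 5),
    m10 = substr(consensus_iupac(block_pwm), 6, 11)
  )
  model
}

#' Classify promoter calls as early or late and flag activity
#'
#' A call matching a timed up-step (same strand, TSS within
#' `merge_distance` of the step boundary) inherits the step's timing and
#' is marked active (`source = "step"`). Calls without a matched step keep
#' the class of the model that found them (`source = "pwm_rescue"`); they
#' are marked active only when a relaxed-threshold step supports them,
#' otherwise they are reported but flagged inactive — predictions that do
#' not change the transcription profile.
#'
#' @param calls data.frame from [scan_genome()], plus a `class` column
#'   naming the model class that produced each call.
#' @param timed_steps data.frame from [classify_step_timing()] (strict
#'   thresholds).
#' @param relaxed_steps Optional data.frame of steps detected at relaxed
#'   thresholds, used only to mark rescued calls active.
#' @param merge_distance Match tolerance in bp.
#' @return `calls` with `class`, `source` and `active` columns resolved.
#' @export
classify_promoter_class <- function(calls, timed_steps,
                                    relaxed_steps = NULL,
                                    merge_distance = 25L) {
  if (nrow(calls) == 0L) {
    calls$active <- logical(0)
    return(calls)
  }
  up <- timed_steps[timed_steps$direction == "up", , drop = FALSE]
  relax <- if (!is.null(relaxed_steps)) {
    relaxed_steps[relaxed_steps$direction == "up", , drop = FALSE]
  } else NULL
  calls$active <- FALSE
  calls$source <- "pwm_rescue"
  calls$step_position <- NA_real_
  # one-to-one greedy matching by distance: each step supports exactly
  # one call and each call is claimed by at most one step, so secondary
  # motif matches cannot ride along on a true promoter's coverage
  # evidence and two adjacent steps (an early TSS with a late promoter
  # just downstream) keep their identities in either genome orientation
  if (nrow(up) > 0L && nrow(calls) > 0L) {
    d <- abs(outer(up$position, calls$tss, "-"))
    d[outer(up$strand, calls$strand, "!=")] <- Inf
    repeat {
      j <- which.min(d)
      if (!is.finite(d[j]) || d[j] > merge_distance) break
      si <- (j - 1L) %% nrow(up) + 1L
      ci <- (j - 1L) %/% nrow(up) + 1L
      calls$class[ci] <- up$timing[si]
      calls$source[ci] <- "step"
      calls$active[ci] <- TRUE
      calls$step_position[ci] <- up$position[si]
      d[si, ] <- Inf
      d[, ci] <- Inf
    }
  }
  for (i in seq_len(NROW(relax))) {
    d <- abs(calls$tss - relax$position[i])
    d[calls$strand != relax$strand[i]] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= merge_distance &&
        !calls$active[j]) {
      calls$active[j] <- TRUE     # coverage-supported rescue
    }
  }
  calls
}
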