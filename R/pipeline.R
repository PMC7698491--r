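# End-to-end drivers: coverage steps -> promoter models -> genome rescan
# -> terminators -> transcription units.

#' Call promoters from coverage steps and PWM rescanning
#'
#' Up-steps at the early timepoints train the two-box early promoter
#' model; late-only up-steps train the late PWM. Both models rescan the
#' genome at their training-recovery thresholds. Scan hits inherit the
#' timing of a matching step and are flagged active; hits without
#' coverage support are kept but flagged inactive. Up-steps that no scan
#' hit explains are reported as step-only promoter calls, so the call set
#' is the union of coverage evidence and motif evidence.
#'
#' @param genome A [genome_record()].
#' @param tracks Named list of [coverage_track()]s (`"<tp>.<strand>"`).
#' @param timepoints Ordered timepoint labels.
#' @param step_par Strict [step_params()] used for TSS/TTS calling.
#' @param relaxed_par Relaxed [step_params()] used only to mark rescued
#'   scan hits as coverage-supported.
#' @param seed Seed for motif discovery.
#' @param min_windows Minimum training windows to fit a motif model.
#' @param merge_distance Step/call matching tolerance (bp).
#' @return List with `promoters` (call data.frame), `early_model`,
#'   `late_model`, `timed_steps`, `raw_steps`.
#' @export
call_promoters <- function(genome, tracks, timepoints,
                           step_par = step_params(),
                           relaxed_par = step_params(min_fold = 1.5,
                                                     min_high_depth = 5),
                           seed = 1L, min_windows = 5L,
                           merge_distance = 25L) {
  raw <- detect_steps_all(tracks, step_par)
  timed <- classify_step_timing(raw, timepoints,
                                merge_distance = merge_distance)
  relaxed <- detect_steps_all(tracks, relaxed_par)
  timed <- add_residual_late_steps(timed, tracks, timepoints, step_par,
                                   merge_distance)

  fit_calls <- function(timing, fit_fun, class) {
    up <- timed[timed$direction == "up" & timed$timing == timing, , drop = FALSE]
    wins <- extract_upstream_windows(genome, up, 100L)
    wins <- wins[!wins$truncated, , drop = FALSE]
    if (nrow(wins) < min_windows) return(list(model = NULL, calls = NULL))
    # canonical window order makes seeded discovery independent of the
    # genomic orientation the windows were collected in
    model <- fit_fun(sort(wins$sequence))
    calls <- scan_genome(model, genome)
    if (nrow(calls)) calls$class <- class
    list(model = model, calls = calls)
  }
  early <- fit_calls("early", function(w) build_early_model(w, seed = seed),
                     "early")
  late <- fit_calls("late", function(w) {
    discover_motif(w, width = 10L, seed = seed + 1L)
  }, "late")

  calls <- rbind(early$calls, late$calls)
  if (!is.null(calls) && nrow(calls)) {
    calls <- dedupe_calls(calls, timed, collapse = 5L,
                          merge_distance = merge_distance)
    calls <- classify_promoter_class(calls, timed, relaxed, merge_distance)
  } else {
    calls <- data.frame(tss = integer(), strand = character(),
                        score = numeric(), spacer = integer(),
                        box10_start = integer(), box10_end = integer(),
                        source = character(), class = character(),
                        active = logical(), step_position = numeric())
  }
  # step-only calls for up-steps no scan hit claimed
  up <- timed[timed$direction == "up", , drop = FALSE]
  claimed <- with(calls[!is.na(calls$step_position), ],
                  paste(strand, step_position))
  for (i in seq_len(nrow(up))) {
    if (!(paste(up$strand[i], up$position[i]) %in% claimed)) {
      calls <- rbind(calls, data.frame(
        tss = up$position[i], strand = up$strand[i], score = NA_real_,
        spacer = NA_integer_, box10_start = NA_integer_,
        box10_end = NA_integer_, source = "step", class = up$timing[i],
        active = TRUE, step_position = up$position[i]))
    }
  }
  calls <- calls[order(calls$tss), , drop = FALSE]
  calls$id <- ifelse(calls$class == "late",
                     paste0("pL", seq_len(nrow(calls))),
                     paste0("p", seq_len(nrow(calls))))
  rownames(calls) <- NULL
  list(promoters = calls, early_model = early$model, late_model = late$model,
       timed_steps = timed, raw_steps = raw)
}

# A late promoter firing inside an already-transcribed unit produces
# only a modest fold change on the raw late-phase track because early
# transcription is still running through it. The diagnostic signal is a
# step in the *ratio* of late-phase to pooled early-phase coverage: the
# ratio is flat across a unit transcribed at constant relative intensity
# but jumps where a late promoter adds depth only at the last timepoint.
# Ratio up-steps (with an absolute late-contribution floor) that do not
# coincide with an already-timed step become extra late TSS candidates.
add_residual_late_steps <- function(timed, tracks, timepoints, step_par,
                                    merge_distance) {
  last_tp <- timepoints[length(timepoints)]
  early_tp <- timepoints[-length(timepoints)]
  extra <- list()
  w <- step_par$w
  eps <- step_par$eps
  for (strand in c("+", "-")) {
    late_trk <- tracks[[paste(last_tp, strand, sep = ".")]]
    if (is.null(late_trk)) next
    base <- rowMeans(vapply(early_tp, function(tp) {
      tracks[[paste(tp, strand, sep = ".")]]$depth
    }, numeric(length(late_trk$depth))))
    L <- length(base)
    if (2L * w > L) next
    csl <- cumsum(c(0, late_trk$depth))
    csb <- cumsum(c(0, base))
    p <- w:(L - w)
    l_late <- (csl[p + 1L] - csl[p - w + 1L]) / w
    r_late <- (csl[p + w + 1L] - csl[p + 1L]) / w
    l_base <- (csb[p + 1L] - csb[p - w + 1L]) / w
    r_base <- (csb[p + w + 1L] - csb[p + 1L]) / w
    ratio_l <- (l_late + eps) / (l_base + eps)
    ratio_r <- (r_late + eps) / (r_base + eps)
    # in transcription sense the late contribution lies 3' of the TSS:
    # right of the boundary on "+", left of it on "-"
    if (strand == "+") {
      foldq <- ratio_r / ratio_l
      excess <- r_late - r_base
    } else {
      foldq <- ratio_l / ratio_r
      excess <- l_late - l_base
    }
    keep <- foldq >= step_par$min_fold &
      excess >= step_par$min_high_depth
    if (!any(keep)) next
    cand <- data.frame(position = p[keep], fold = foldq[keep],
                       high = excess[keep])
    cand <- cand[order(-cand$fold, cand$position), , drop = FALSE]
    taken <- numeric(0)
    radius <- max(step_par$merge_distance, w)
    for (i in seq_len(nrow(cand))) {
      if (length(taken) &&
          min(abs(taken - cand$position[i])) < radius) next
      taken <- c(taken, cand$position[i])
      # suppress duplicates of steps already timed: the same late TSS
      # found on the raw last-timepoint track sits within a few bp; a
      # *different* late promoter can legitimately sit just downstream
      # of an early TSS, so the wide radius applies only to late steps
      up_here <- timed[timed$strand == strand & timed$direction == "up", ,
                       drop = FALSE]
      d <- abs(up_here$position - cand$position[i])
      if (any(d <= 10L) ||
          any(d <= merge_distance & up_here$timing == "late")) next
      extra[[length(extra) + 1L]] <- data.frame(
        position = cand$position[i], direction = "up", strand = strand,
        fold = cand$fold[i], high_side_depth = cand$high[i],
        timing = "late", timepoints = last_tp, stringsAsFactors = FALSE)
    }
  }
  if (length(extra)) {
    timed <- rbind(timed, do.call(rbind, extra))
    timed <- timed[order(timed$strand, timed$position), , drop = FALSE]
    rownames(timed) <- NULL
  }
  timed
}

# Resolve near-duplicate calls from the two models (same strand, TSS
# within `collapse` bp): a call whose class agrees with a matched step
# wins; otherwise the early call does (a -35 box argues for sigma-70
# recognition); ties by score.
dedupe_calls <- function(calls, timed, collapse = 5L, merge_distance = 25L) {
  if (nrow(calls) < 2L) return(calls)
  pref <- integer(nrow(calls))
  up <- timed[timed$direction == "up", , drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    m <- up[up$strand == calls$strand[i] &
              abs(up$position - calls$tss[i]) <= merge_distance, , drop = FALSE]
    agree <- nrow(m) > 0L && any(m$timing == calls$class[i])
    pref[i] <- 2L * agree + (calls$class[i] == "early")
  }
  ord <- order(-pref, -ifelse(is.na(calls$score), -Inf, calls$score))
  keep <- logical(nrow(calls))
  taken <- list(`+` = numeric(0), `-` = numeric(0))
  for (i in ord) {
    s <- calls$strand[i]
    if (!length(taken[[s]]) || min(abs(taken[[s]] - calls$tss[i])) > collapse) {
      keep[i] <- TRUE
      taken[[s]] <- c(taken[[s]], calls$tss[i])
    }
  }
  calls[keep, , drop = FALSE]
}

#' Infer the full transcriptional landscape
#'
#' Runs step detection, promoter model fitting and rescanning, terminator
#' calling and TU assembly in one pass.
#'
#' @inheritParams call_promoters
#' @param orfs ORF data.frame (`id`, `start`, `end`, `strand`).
#' @param term_par A [terminator_params()] object.
#' @param closure_readthrough TU-closing readthrough threshold.
#' @return A list of class `phage_landscape`: `promoters`, `terminators`,
#'   `landscape` (the [assemble_tus()] result), `timed_steps`, the fitted
#'   models and the summary `report`.
#' @export
infer_landscape <- function(genome, orfs, tracks, timepoints,
                            step_par = step_params(),
                            term_par = terminator_params(),
                            closure_readthrough = 0.5,
                            seed = 1L) {
  pc <- call_promoters(genome, tracks, timepoints, step_par = step_par,
                       seed = seed)
  terms <- call_terminators(genome, pc$timed_steps, tracks, timepoints,
                            params = term_par)
  landscape <- assemble_tus(orfs, pc$promoters, terms, genome$length,
                            closure_readthrough = closure_readthrough)
  structure(
    list(promoters = pc$promoters, terminators = terms,
         landscape = landscape, timed_steps = pc$timed_steps,
         early_model = pc$early_model, late_model = pc$late_model,
         report = landscape_report(landscape)),
    class = "phage_landscape"
  )
}

#' @export
print.phage_landscape <- function(x, ...) {
  cat("<phage_landscape>", nrow(x$promoters), "promoter calls (",
      sum(x$promoters$active), "active ),", nrow(x$terminators),
      "terminators,", x$report$n_tus, "TUs\n")
  invisible(x)
}

#' Write landscape results to disk
#'
#' Emits promoters and terminators as GFF3 and TSV, steps as BED6 (score
#' = fold x 100 capped at 1000) and the TU table as GFF3 + TSV.
#'
#' @param result A `phage_landscape` from [infer_landscape()].
#' @param dir Output directory.
#' @param seqname Sequence name for the GFF3/BED columns.
#' @export
export_landscape <- function(result, dir, seqname = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- result$timed_steps
  bed <- data.frame(chrom = seqname, start = st$position,
                    end = st$position + 1L,
                    name = paste0(st$direction, "_", st$timing),
                    score = pmin(round(st$fold * 100), 1000),
                    strand = st$strand)
  utils::write.table(bed, file.path(dir, "steps.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pr <- result$promoters
  pr_feat <- data.frame(id = pr$id,
                        start = ifelse(pr$strand == "+", pr$tss, pr$tss - 1L),
                        end = ifelse(pr$strand == "+", pr$tss + 1L, pr$tss),
                        strand = pr$strand, class = pr$class,
                        source_kind = pr$source, active = pr$active)
  write_gff(pr_feat, file.path(dir, "promoters.gff3"), seqname = seqname,
            type = "promoter")
  utils::write.table(pr, file.path(dir, "promoters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tm <- result$terminators
  if (nrow(tm)) {
    tm_feat <- data.frame(id = paste0("t", seq_len(nrow(tm))),
                          start = ifelse(tm$strand == "+", tm$position - 1L,
                                         tm$position),
                          end = ifelse(tm$strand == "+", tm$position,
                                       tm$position + 1L),
                          strand = tm$strand, stem = tm$stem_len,
                          loop = tm$loop_len, polyT = tm$polyT_len,
                          hairpin_score = tm$hairpin_score,
                          readthrough = round(tm$readthrough, 3))
    write_gff(tm_feat, file.path(dir, "terminators.gff3"), seqname = seqname,
              type = "terminator")
  }
  utils::write.table(tm, file.path(dir, "terminators.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tus <- result$landscape$tus
  if (nrow(tus)) {
    tu_feat <- data.frame(id = tus$id,
                          start = pmin(tus$tss, tus$end),
                          end = pmax(tus$tss, tus$end),
                          strand = tus$strand, class = tus$class,
                          n_orfs = tus$n_orfs)
    write_gff(tu_feat, file.path(dir, "transcription_units.gff3"),
              seqname = seqname, type = "transcription_unit")
  }
  utils::write.table(tus, file.path(dir, "transcription_units.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
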