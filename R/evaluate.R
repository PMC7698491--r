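# Recovery metrics against a planted architecture: these quantify how
# well the inference reconstructs a simulation's ground truth.

# Match called positions against truth positions on the same strand
# within `tol` bp; one-to-one greedy matching by distance.
match_positions <- function(truth, called, tol) {
  if (nrow(truth) == 0L || nrow(called) == 0L) {
    return(list(tp = 0L, truth_hit = logical(nrow(truth)),
                called_hit = logical(nrow(called))))
  }
  truth_hit <- logical(nrow(truth))
  called_hit <- logical(nrow(called))
  d <- abs(outer(truth$pos, called$pos, "-"))
  d[outer(truth$strand, called$strand, "!=")] <- Inf
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)
    if (!is.finite(d[m[1, 1], m[1, 2]]) || d[m[1, 1], m[1, 2]] > tol) break
    i <- m[1, 1]; j <- m[1, 2]
    truth_hit[i] <- TRUE; called_hit[j] <- TRUE
    d[i, ] <- Inf; d[, j] <- Inf
  }
  list(tp = sum(truth_hit), truth_hit = truth_hit, called_hit = called_hit)
}

#' Promoter recovery against a planted architecture
#'
#' Sensitivity is the fraction of planted promoters recovered by any
#' call; precision is the fraction of coverage-supported (active) calls
#' that correspond to a planted promoter. Calls flagged inactive are
#' speculative motif matches and are excluded from precision, mirroring
#' how predictions without transcriptional support are reported apart.
#'
#' @param architecture The generating `phage_architecture`.
#' @param promoters Promoter calls (from [call_promoters()]).
#' @param tol Position tolerance in bp.
#' @return List `sensitivity`, `precision`, `n_truth`, `n_called_active`,
#'   `class_agreement` (fraction of matched planted promoters whose call
#'   class is correct).
#' @export
evaluate_promoter_recovery <- function(architecture, promoters, tol = 10L) {
  truth <- data.frame(pos = architecture$promoters$tss,
                      strand = architecture$promoters$strand,
                      class = architecture$promoters$class)
  called <- data.frame(pos = promoters$tss, strand = promoters$strand,
                       class = promoters$class,
                       active = if (!is.null(promoters$active)) promoters$active else TRUE)
  m_all <- match_positions(truth, called, tol)
  active <- called[called$active, , drop = FALSE]
  m_act <- match_positions(truth, active, tol)
  cls <- NA_real_
  if (m_all$tp > 0) {
    d <- abs(outer(truth$pos, called$pos, "-"))
    d[outer(truth$strand, called$strand, "!=")] <- Inf
    hit <- which(m_all$truth_hit)
    cls <- mean(vapply(hit, function(i) {
      j <- which.min(d[i, ])
      called$class[j] == truth$class[i]
    }, logical(1)))
  }
  list(sensitivity = m_all$tp / max(nrow(truth), 1L),
       precision = if (nrow(active)) m_act$tp / nrow(active) else NA_real_,
       n_truth = nrow(truth), n_called_active = nrow(active),
       class_agreement = cls)
}

#' Terminator recovery against a planted architecture
#'
#' @param architecture The generating `phage_architecture`.
#' @param terminators Terminator calls (from [call_terminators()]).
#' @param tol Position tolerance in bp.
#' @return List `sensitivity`, `precision`, `n_truth`, `n_called`,
#'   `readthrough_rmse` (matched calls, last timepoint vs planted).
#' @export
evaluate_terminator_recovery <- function(architecture, terminators, tol = 10L) {
  truth <- data.frame(pos = architecture$terminators$pos,
                      strand = architecture$terminators$strand,
                      rt = architecture$terminators$readthrough)
  called <- data.frame(pos = terminators$position, strand = terminators$strand,
                       rt = terminators$readthrough)
  m <- match_positions(truth, called, tol)
  rmse <- NA_real_
  if (m$tp > 0) {
    d <- abs(outer(truth$pos, called$pos, "-"))
    d[outer(truth$strand, called$strand, "!=")] <- Inf
    hit <- which(m$truth_hit)
    err <- vapply(hit, function(i) {
      j <- which.min(d[i, ])
      called$rt[j] - truth$rt[i]
    }, numeric(1))
    rmse <- sqrt(mean(err^2, na.rm = TRUE))
  }
  list(sensitivity = m$tp / max(nrow(truth), 1L),
       precision = if (nrow(called)) m$tp / nrow(called) else NA_real_,
       n_truth = nrow(truth), n_called = nrow(called),
       readthrough_rmse = rmse)
}

#' Transcription-unit recovery against a planted architecture
#'
#' For each planted TU the best-matching assembled TU is found by
#' Jaccard similarity of ORF memberships; the score is the mean best
#' Jaccard, and class accuracy is the fraction of planted TUs whose best
#' match carries the correct temporal class.
#'
#' @param architecture The generating `phage_architecture`.
#' @param landscape A `tu_landscape` from [assemble_tus()].
#' @return List `jaccard`, `class_accuracy`, `n_truth`, `n_assembled`.
#' @export
evaluate_tu_recovery <- function(architecture, landscape) {
  truth_sets <- split(architecture$orfs$id, architecture$orfs$tu)
  pred <- landscape$orf_assignment
  pred_sets <- split(names(pred)[!is.na(pred)], pred[!is.na(pred)])
  pred_class <- stats::setNames(landscape$tus$class, landscape$tus$id)
  truth_class <- stats::setNames(architecture$tus$class, architecture$tus$id)
  jac <- vapply(names(truth_sets), function(tu) {
    ts <- truth_sets[[tu]]
    if (!length(pred_sets)) return(0)
    max(vapply(pred_sets, function(ps) {
      length(intersect(ts, ps)) / length(union(ts, ps))
    }, numeric(1)))
  }, numeric(1))
  cls <- vapply(names(truth_sets), function(tu) {
    ts <- truth_sets[[tu]]
    if (!length(pred_sets)) return(FALSE)
    j <- vapply(pred_sets, function(ps) {
      length(intersect(ts, ps)) / length(union(ts, ps))
    }, numeric(1))
    best <- names(pred_sets)[which.max(j)]
    max(j) > 0 && identical(unname(pred_class[best]), unname(truth_class[tu]))
  }, logical(1))
  list(jaccard = mean(jac), class_accuracy = mean(cls),
       n_truth = length(truth_sets), n_assembled = nrow(landscape$tus))
}
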