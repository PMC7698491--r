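# Assembly of promoters, terminators and ORFs into strand-wise
# transcription units and the landscape summary.

#' Assemble transcription units
#'
#' Each strand is walked 5' to 3' in transcription direction. A TU opens
#' at the first (active) promoter not inside an open TU, extends over
#' co-oriented ORFs starting downstream of the TSS, and closes at the
#' first terminator that follows at least one ORF and whose late-phase
#' readthrough is below `closure_readthrough`; terminators above that
#' threshold are recorded but transcription is considered continuing.
#' Promoters met inside an open TU become internal promoters. Promoters
#' with no ORF before the closing terminator are reported as orphans and
#' form no unit.
#'
#' @param orfs data.frame `id`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @param promoters Promoter calls with `tss`, `strand`, `class`, and
#'   optionally `active` (inactive calls are ignored) and `id`.
#' @param terminators Terminator calls with `position`, `strand`,
#'   `readthrough`.
#' @param genome_length Genome length in bp.
#' @param closure_readthrough Readthrough below which a terminator closes
#'   its TU.
#' @return A list of class `tu_landscape`: `tus` (one row per TU with
#'   `id`, `strand`, `class`, `tss`, `end`, `n_orfs`, `n_promoters`,
#'   `n_terminators`), `orf_assignment` (`id` -> `tu`, NA when
#'   unassigned), `orphan_promoters`, and the inputs annotated with their
#'   TU.
#' @export
assemble_tus <- function(orfs, promoters, terminators, genome_length,
                         closure_readthrough = 0.5) {
  if (!is.null(promoters$active)) {
    promoters <- promoters[promoters$active, , drop = FALSE]
  }
  if (is.null(promoters$id)) {
    promoters$id <- paste0("p", seq_len(nrow(promoters)))
  }
  tus <- list(); orphan <- list()
  orf_tu <- stats::setNames(rep(NA_character_, nrow(orfs)), orfs$id)
  prom_tu <- stats::setNames(rep(NA_character_, nrow(promoters)), promoters$id)
  term_tu <- rep(NA_character_, nrow(terminators))
  n_tu <- 0L
  for (strand in c("+", "-")) {
    items <- rbind(
      if (nrow(promoters)) {
        p <- promoters[promoters$strand == strand, , drop = FALSE]
        if (nrow(p)) data.frame(kind = "prom", key = p$tss, idx = which(promoters$strand == strand))
      },
      if (nrow(terminators)) {
        t_ <- terminators[terminators$strand == strand, , drop = FALSE]
        if (nrow(t_)) data.frame(kind = "term", key = t_$position, idx = which(terminators$strand == strand))
      },
      if (nrow(orfs)) {
        o <- orfs[orfs$strand == strand, , drop = FALSE]
        if (nrow(o)) data.frame(kind = "orf",
                                key = if (strand == "+") o$start else o$end,
                                idx = which(orfs$strand == strand))
      }
    )
    if (is.null(items) || nrow(items) == 0L) next
    # transcription order; at equal keys promoters come before ORFs
    kind_rank <- match(items$kind, c("prom", "orf", "term"))
    items <- items[order(items$key * if (strand == "+") 1 else -1, kind_rank), ,
                   drop = FALSE]
    open <- FALSE
    cur <- NULL
    close_tu <- function(cur, term_idx) {
      n_tu <<- n_tu + 1L
      id <- sprintf("TU%02d", n_tu)
      orf_tu[cur$orfs] <<- id
      prom_tu[cur$proms] <<- id
      if (!is.null(term_idx)) term_tu[term_idx] <<- id
      tus[[id]] <<- data.frame(
        id = id, strand = strand,
        class = classify_tu(promoters$class[match(cur$proms, promoters$id)]),
        tss = cur$tss, end = cur$end,
        n_orfs = length(cur$orfs), n_promoters = length(cur$proms),
        n_terminators = length(term_idx), stringsAsFactors = FALSE
      )
    }
    for (r in seq_len(nrow(items))) {
      kind <- items$kind[r]; idx <- items$idx[r]; key <- items$key[r]
      if (kind == "prom") {
        if (!open) {
          open <- TRUE
          cur <- list(proms = promoters$id[idx], orfs = character(),
                      terms = integer(), tss = key, end = NA)
        } else {
          cur$proms <- c(cur$proms, promoters$id[idx])
        }
      } else if (kind == "orf") {
        if (open) cur$orfs <- c(cur$orfs, orfs$id[idx])
      } else { # terminator
        if (!open) next
        rt <- terminators$readthrough[idx]
        closes <- is.na(rt) || rt < closure_readthrough
        if (!closes) {
          cur$terms <- c(cur$terms, idx)
          next
        }
        if (length(cur$orfs) == 0L) {
          orphan[[length(orphan) + 1L]] <- data.frame(
            promoter = cur$proms, strand = strand, stringsAsFactors = FALSE)
        } else {
          cur$end <- key
          close_tu(cur, c(cur$terms, idx))
        }
        open <- FALSE
        cur <- NULL
      }
    }
    if (open && length(cur$orfs) > 0L) {
      # ran off the strand end without a closing terminator
      cur$end <- if (strand == "+") genome_length else 0L
      close_tu(cur, cur$terms)
    } else if (open && length(cur$proms) > 0L) {
      orphan[[length(orphan) + 1L]] <- data.frame(
        promoter = cur$proms, strand = strand, stringsAsFactors = FALSE)
    }
  }
  tus_df <- if (length(tus)) do.call(rbind, tus) else
    data.frame(id = character(), strand = character(), class = character(),
               tss = numeric(), end = numeric(), n_orfs = integer(),
               n_promoters = integer(), n_terminators = integer())
  rownames(tus_df) <- NULL
  structure(
    list(tus = tus_df,
         orf_assignment = orf_tu,
         promoter_assignment = prom_tu,
         terminator_assignment = term_tu,
         orphan_promoters = if (length(orphan)) do.call(rbind, orphan) else
           data.frame(promoter = character(), strand = character()),
         orfs = orfs, promoters = promoters, terminators = terminators),
    class = "tu_landscape"
  )
}

#' Temporal class of a transcription unit from its promoter classes
#'
#' @param promoter_classes Character vector of `early`/`late`.
#' @return `"early"` when only early promoters drive the unit, `"late"`
#'   when only late ones, `"both"` when at least one of each.
#' @export
classify_tu <- function(promoter_classes) {
  promoter_classes <- promoter_classes[!is.na(promoter_classes)]
  if (length(promoter_classes) == 0L) stop("TU with no promoters")
  has_e <- any(promoter_classes == "early")
  has_l <- any(promoter_classes == "late")
  if (has_e && has_l) "both" else if (has_e) "early" else "late"
}

#' Summarize a transcription landscape
#'
#' @param landscape A `tu_landscape` from [assemble_tus()].
#' @return A list with `by_class` and `by_strand` count/percentage
#'   tables (percentages as `round(100 k/n, 1)`), `n_tus`, `n_orfs_assigned`,
#'   `unassigned_orfs`, and the per-TU table.
#' @export
landscape_report <- function(landscape) {
  tus <- landscape$tus
  n <- nrow(tus)
  tab <- function(x, levels) {
    k <- vapply(levels, function(l) sum(x == l), integer(1))
    data.frame(level = levels, n = k,
               percent = if (n > 0) round(100 * k / n, 1) else 0)
  }
  list(
    n_tus = n,
    by_class = tab(tus$class, c("early", "late", "both")),
    by_strand = tab(tus$strand, c("+", "-")),
    n_orfs_assigned = sum(!is.na(landscape$orf_assignment)),
    unassigned_orfs = names(landscape$orf_assignment)[is.na(landscape$orf_assignment)],
    tus = tus
  )
}

#' @export
print.tu_landscape <- function(x, ...) {
  r <- landscape_report(x)
  cat("<tu_landscape>", r$n_tus, "TUs (",
      paste(sprintf("%s: %d", r$by_class$level, r$by_class$n), collapse = ", "),
      ");", r$n_orfs_assigned, "ORFs assigned\n")
  invisible(x)
}
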