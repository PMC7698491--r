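# Count normalization (TMM, GeTMM), intergenic-region quantification,
# negative-binomial differential tests with BH FDR, and temporal
# expression classes.

#' Construct a count matrix object
#'
#' @param counts Non-negative integer matrix, features x samples, with
#'   rownames.
#' @param lengths Named feature lengths in bp (> 0).
#' @param samples data.frame with one row per column of `counts`, columns
#'   `timepoint` and `replicate`.
#' @return A list of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs rownames")
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("every feature needs a positive length")
  }
  if (nrow(samples) != ncol(counts)) stop("samples/counts dimension mismatch")
  if (any(counts < 0)) stop("negative counts")
  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' Read a counts TSV (id, length, then one column per sample)
#'
#' Sample columns are expected as `<timepoint>_r<replicate>`.
#'
#' @param path TSV path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(counts) <- tab[[1]]
  nm <- colnames(counts)
  tp <- sub("_r[0-9]+$", "", nm)
  rep <- sub("^.*_r", "", nm)
  count_matrix(counts, stats::setNames(tab[[2]], tab[[1]]),
               data.frame(timepoint = tp, replicate = rep))
}

#' Pairwise trimmed-mean-of-M-values normalization factor
#'
#' Per-gene log-ratios (M) and log-abundances (A) on library-size-scaled
#' counts, genes with a zero in either sample excluded, doubly trimmed
#' (`trim_M` of the M tails, `trim_A` of the A tails), and averaged with
#' inverse asymptotic binomial variance weights; the factor is
#' `2^weighted_mean`.
#'
#' @param obs Counts of the sample being normalized.
#' @param ref Counts of the reference sample (same gene order).
#' @param trim_M Two-sided trim fraction on M.
#' @param trim_A Two-sided trim fraction on A.
#' @param do_weighting Use precision weights (TRUE, the standard form).
#' @return Positive scalar factor.
#' @export
tmm_factor <- function(obs, ref, trim_M = 0.30, trim_A = 0.05,
                       do_weighting = TRUE) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  if (length(obs) != length(ref)) stop("obs/ref length mismatch")
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L) stop("no genes left after removing zeros")
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_M) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * trim_A) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  if (!any(keep)) stop("all genes trimmed")
  f <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (is.na(f)) f <- 0
  2^f
}

#' Per-sample TMM factors, rescaled to geometric mean 1
#'
#' The reference sample is the one whose 75th count percentile (scaled by
#' library size) is closest to the mean across samples.
#'
#' @param counts Feature x sample count matrix.
#' @param ref Optional reference column index.
#' @return Numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, ref = NULL) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  lib <- colSums(counts)
  if (is.null(ref)) {
    f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else tmm_factor(counts[, j], counts[, ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' Gene-length-corrected TMM (GeTMM) normalization
#'
#' Counts are converted to reads per kilobase (RPK), TMM factors are
#' computed on the RPK matrix, and each sample is scaled to
#' counts-per-million of effective RPK library size, so values are
#' comparable both across samples and across genes of different length.
#'
#' @param cm A [count_matrix()].
#' @return A list of class `normalized_expression`: `values` (GeTMM
#'   matrix), `factors`, `lib_sizes` (RPK library sizes), `samples`.
#' @export
getmm <- function(cm) {
  if (any(cm$lengths <= 0)) stop("zero-length gene")
  expressed <- rowSums(cm$counts) > 0
  counts <- cm$counts[expressed, , drop = FALSE]
  rpk <- counts / (cm$lengths[expressed] / 1000)
  factors <- tmm_factors(rpk)
  lib <- colSums(rpk)
  values <- sweep(rpk, 2, lib * factors, "/") * 1e6
  structure(list(values = values, factors = factors, lib_sizes = lib,
                 samples = cm$samples),
            class = "normalized_expression")
}

#' Share of normalized expression attributed to named regions
#'
#' @param norm A `normalized_expression` (or a plain values matrix).
#' @param region_ids Feature ids of the regions.
#' @return Percentage (0-100) of total normalized values in the regions.
#' @export
region_fraction <- function(norm, region_ids) {
  values <- if (inherits(norm, "normalized_expression")) norm$values else norm
  missing_ids <- setdiff(region_ids, rownames(values))
  if (length(missing_ids)) {
    stop("unknown region id(s): ", paste(missing_ids, collapse = ", "))
  }
  100 * sum(values[region_ids, , drop = FALSE]) / sum(values)
}

# Method-of-moments common NB dispersion from library-equalized counts.
common_dispersion <- function(pseudo, groups) {
  num <- 0; den <- 0
  for (g in unique(groups)) {
    x <- pseudo[, groups == g, drop = FALSE]
    if (ncol(x) < 2L) next
    m <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  if (den <= 0) return(0)
  max(num / den, 0)
}

# Exact conditional double-tail test for two groups of NB counts with
# equal underlying means under H0 and common dispersion phi. Conditional
# on the total, the group-A sum follows a negative hypergeometric law
# free of the mean; phi = 0 degenerates to the conditional binomial.
nb_exact_test <- function(sum_a, sum_b, n_a, n_b, phi) {
  t <- sum_a + sum_b
  if (t == 0) return(1)
  a <- 0:t
  logp <- if (phi > 1e-12) {
    rA <- n_a / phi; rB <- n_b / phi
    lgamma(a + rA) - lgamma(a + 1) +
      lgamma(t - a + rB) - lgamma(t - a + 1)
  } else {
    stats::dbinom(a, t, n_a / (n_a + n_b), log = TRUE)
  }
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  min(1, sum(p[p <= p[sum_a + 1] * (1 + 1e-8)]))
}

#' Two-group differential expression test
#'
#' TMM-normalized libraries, a common method-of-moments negative-binomial
#' dispersion, an exact conditional test per gene (Poisson/binomial
#' fallback when dispersion is zero or replication is absent), and BH
#' adjustment across genes.
#'
#' @param cm A [count_matrix()].
#' @param group_a,group_b Sample selectors: column indices, or timepoint
#'   labels matched against `cm$samples$timepoint`.
#' @param fdr Significance cutoff on the BH-adjusted p-value.
#' @return data.frame `id`, `logFC` (a over b), `pvalue`, `fdr`,
#'   `significant`.
#' @export
differential <- function(cm, group_a, group_b, fdr = 0.01) {
  sel <- function(g) {
    if (is.character(g)) which(cm$samples$timepoint %in% g) else as.integer(g)
  }
  ia <- sel(group_a); ib <- sel(group_b)
  if (!length(ia) || !length(ib)) stop("empty group")
  counts <- cm$counts[, c(ia, ib), drop = FALSE]
  expressed <- rowSums(counts) > 0
  sub <- counts[expressed, , drop = FALSE]
  groups <- rep(c("a", "b"), c(length(ia), length(ib)))
  factors <- tmm_factors(sub)
  eff_lib <- colSums(sub) * factors
  common <- exp(mean(log(eff_lib)))
  pseudo <- round(sweep(sub, 2, common / eff_lib, "*"))
  phi <- common_dispersion(pseudo, groups)
  sa <- rowSums(pseudo[, groups == "a", drop = FALSE])
  sb <- rowSums(pseudo[, groups == "b", drop = FALSE])
  pvals <- vapply(seq_len(nrow(pseudo)), function(i) {
    nb_exact_test(sa[i], sb[i], sum(groups == "a"), sum(groups == "b"), phi)
  }, numeric(1))
  cpm <- sweep(sub, 2, eff_lib, "/") * 1e6
  ma <- rowMeans(cpm[, groups == "a", drop = FALSE])
  mb <- rowMeans(cpm[, groups == "b", drop = FALSE])
  logfc <- log2((ma + 0.5) / (mb + 0.5))
  adj <- stats::p.adjust(pvals, method = "BH")
  out <- data.frame(id = rownames(cm$counts), logFC = NA_real_,
                    pvalue = NA_real_, fdr = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  idx <- match(rownames(sub), out$id)
  out$logFC[idx] <- logfc
  out$pvalue[idx] <- pvals
  out$fdr[idx] <- adj
  out$significant[idx] <- adj <= fdr
  out
}

#' Temporal expression class per gene
#'
#' *late-expressed*: significantly up at the last timepoint versus the
#' pooled earlier ones and essentially silent at the first timepoint
#' (below the `floor_quantile` of first-timepoint values);
#' *early-expressed*: expressed at the first timepoint; *flat*:
#' everything else.
#'
#' @param norm A `normalized_expression` from [getmm()].
#' @param diff_late Result of [differential()] contrasting the last
#'   timepoint against the pooled earlier ones (`group_a` = last).
#' @param floor_quantile Quantile of positive first-timepoint values
#'   separating "silent" from "expressed".
#' @param floor_min Absolute lower bound for the floor.
#' @return Named character vector: `early-expressed`, `late-expressed` or
#'   `flat`.
#' @export
temporal_profile <- function(norm, diff_late, floor_quantile = 0.2,
                             floor_min = 1) {
  tps <- unique(norm$samples$timepoint)
  first <- norm$samples$timepoint == tps[1]
  v1 <- rowMeans(norm$values[, first, drop = FALSE])
  floor <- max(stats::quantile(v1[v1 > 0], floor_quantile, names = FALSE),
               floor_min)
  out <- stats::setNames(rep("flat", nrow(norm$values)), rownames(norm$values))
  d <- diff_late[match(names(out), diff_late$id), ]
  late <- !is.na(d$significant) & d$significant & d$logFC > 0 & v1 < floor
  out[late] <- "late-expressed"
  out[!late & v1 >= floor] <- "early-expressed"
  out
}
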