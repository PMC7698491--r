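# Promoter motif discovery (ZOOPS EM), PWM construction and scoring,
# IUPAC consensus, training-recovery thresholding and genome rescanning.
#
# Early promoters are modeled as a -35 hexamer plus an 11-column
# ext/-10 block (TRTGN + TATANT) separated by a 16-18 bp spacer; late
# promoters as a single block around the long TGTTATATTA -10 motif. The
# TSS sits 6 bp downstream of the -10 box 3' end (5 nt gap).

#' Build a position weight matrix from aligned sites
#'
#' @param sites Character vector of equal-length sites over `A,C,G,T`.
#' @param pseudocount Laplace pseudocount added per base and column.
#' @param background Background base frequencies `(A,C,G,T)`, summing
#'   to 1.
#' @return An object of class `pwm_model` with count, probability and
#'   base-2 log-odds matrices.
#' @export
build_pwm <- function(sites, pseudocount = 1, background = rep(0.25, 4)) {
  if (length(sites) == 0L) stop("no sites")
  sites <- toupper(sites)
  wds <- unique(nchar(sites))
  if (length(wds) != 1L) stop("sites have unequal lengths")
  width <- wds
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  mat <- vapply(sites, seq_to_int, integer(width))
  if (any(is.na(mat))) stop("sites must be plain ACGT")
  counts <- matrix(0, 4, width, dimnames = list(BASES, NULL))
  for (j in seq_len(width)) {
    tab <- tabulate(mat[j, ], nbins = 4)
    counts[, j] <- tab
  }
  prob <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  logodds <- log2(prob / background)
  structure(
    list(width = width, counts = counts, prob = prob, logodds = logodds,
         pseudocount = pseudocount, background = background,
         n_sites = length(sites), threshold = NA_real_, tss_offset = 5L),
    class = "pwm_model"
  )
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("<pwm_model> width", x$width, "from", x$n_sites, "sites; consensus",
      consensus_iupac(x), "\n")
  invisible(x)
}

#' Score sites against a PWM
#'
#' @param pwm A [build_pwm()] model.
#' @param sites Character vector of sequences of the PWM's width.
#' @return Numeric vector of log-odds scores (bits); sites containing
#'   non-ACGT letters score `-Inf`.
#' @export
pwm_score <- function(pwm, sites) {
  vapply(toupper(sites), function(s) {
    x <- seq_to_int(s)
    if (length(x) != pwm$width) stop("site length != PWM width")
    if (any(is.na(x))) return(-Inf)
    # accumulate column by column in double precision, the same order the
    # genome scanner uses, so a training site's score and its scan score
    # are bitwise identical and the training-recovery threshold is exact
    sc <- 0
    for (j in seq_len(pwm$width)) sc <- sc + pwm$logodds[x[j], j]
    sc
  }, numeric(1), USE.NAMES = FALSE)
}

#' Training-recovery threshold of a PWM
#'
#' The score cutoff is set to retrieve every sequence the matrix was
#' built from: the minimum training-site score.
#'
#' @param pwm A `pwm_model`.
#' @param sites The training sites.
#' @return The minimum score over `sites`.
#' @export
training_threshold <- function(pwm, sites) {
  if (length(sites) == 0L) stop("empty training set")
  min(pwm_score(pwm, sites))
}

#' Per-column information content of a PWM (bits)
#' @param pwm A `pwm_model`.
#' @return Numeric vector, one entry per column.
#' @export
pwm_information <- function(pwm) {
  apply(pwm$prob, 2, function(p) sum(ifelse(p > 0, p * log2(p / 0.25), 0)))
}

#' IUPAC consensus string of a PWM
#'
#' Per column: the single majority base when its probability is at least
#' `major_threshold` and at least twice the runner-up; a two-base IUPAC
#' code when the top two sum to at least `pair_threshold`; otherwise `N`.
#'
#' @param pwm A `pwm_model`.
#' @param major_threshold Single-base majority cutoff.
#' @param pair_threshold Two-base cumulative cutoff.
#' @return Consensus string.
#' @export
consensus_iupac <- function(pwm, major_threshold = 0.5, pair_threshold = 0.75) {
  chars <- apply(pwm$prob, 2, function(p) {
    o <- order(p, decreasing = TRUE)
    if (p[o[1]] >= major_threshold && p[o[1]] >= 2 * p[o[2]]) {
      BASES[o[1]]
    } else if (p[o[1]] + p[o[2]] >= pair_threshold) {
      key <- paste(sort(BASES[o[1:2]]), collapse = "")
      IUPAC_PAIRS[[key]]
    } else {
      "N"
    }
  })
  paste(chars, collapse = "")
}

# Score every 0-based start position of an integer-coded sequence.
# Positions overlapping non-ACGT letters score -Inf.
score_positions <- function(logodds, x) {
  width <- ncol(logodds)
  n <- length(x) - width + 1L
  if (n < 1L) return(numeric(0))
  lo <- rbind(logodds, rep(-Inf, width))
  xi <- ifelse(is.na(x), 5L, x)
  s <- numeric(n)
  for (j in seq_len(width)) {
    s <- s + lo[cbind(xi[j:(j + n - 1L)], j)]
  }
  s
}

#' Discover a motif in sequence windows by ZOOPS EM
#'
#' Expectation-maximisation over the latent site position per window
#' (zero-or-one site per window), best of `n_restarts` random
#' initialisations by log-likelihood. Deterministic given `seed`.
#'
#' @param windows Character vector of sequences (>= 5, each at least
#'   `width` long).
#' @param width Motif width.
#' @param n_restarts Number of EM restarts.
#' @param seed Integer seed.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @return A `pwm_model` built from the maximum-posterior site of each
#'   window that carries one, with fields `sites` (data.frame `window`,
#'   `offset`, `sequence`), `loglik` and a training-recovery `threshold`.
#' @export
discover_motif <- function(windows, width, n_restarts = 20L, seed = 1L,
                           max_iter = 200L, tol = 1e-6) {
  windows <- toupper(windows)
  if (length(windows) < 5L) stop("need at least 5 windows")
  if (width > min(nchar(windows))) stop("width exceeds shortest window")
  xs <- lapply(windows, seq_to_int)
  # per-window matrix of site base indices: n_pos x width
  site_idx <- lapply(xs, function(x) {
    n <- length(x) - width + 1L
    m <- vapply(seq_len(width), function(j) x[j:(j + n - 1L)], integer(n))
    matrix(m, nrow = n)
  })
  ok_pos <- lapply(site_idx, function(m) rowSums(is.na(m)) == 0L)
  bg_counts <- tabulate(unlist(xs)[!is.na(unlist(xs))], nbins = 4)
  bg <- (bg_counts + 1) / sum(bg_counts + 1)
  n_win <- length(windows)

  run_em <- function(theta) {
    gamma <- 0.8
    ll_old <- -Inf
    z <- NULL
    for (iter in seq_len(max_iter)) {
      logratio <- log(theta) - log(bg)
      ll <- 0
      z <- vector("list", n_win)
      for (i in seq_len(n_win)) {
        m <- site_idx[[i]]
        n_pos <- nrow(m)
        lr <- rep(-Inf, n_pos)
        idx <- which(ok_pos[[i]])
        if (length(idx)) {
          sub <- m[idx, , drop = FALSE]
          acc <- numeric(length(idx))
          for (j in seq_len(width)) {
            acc <- acc + logratio[cbind(sub[, j], j)]
          }
          lr[idx] <- acc
        }
        mx <- suppressWarnings(max(lr[is.finite(lr)]))
        if (!is.finite(mx)) mx <- 0
        wgt <- exp(lr - mx)
        wgt[!is.finite(wgt)] <- 0
        num <- (gamma / n_pos) * wgt
        den <- (1 - gamma) * exp(-mx) + sum(num)
        ll <- ll + log(den) + mx
        z[[i]] <- num / den
      }
      # M-step: expected letter counts under the site posteriors
      cnt <- matrix(0.25, 4, width)   # small Dirichlet smoothing
      tot_z <- 0
      for (i in seq_len(n_win)) {
        zi <- z[[i]]
        tot_z <- tot_z + sum(zi)
        use <- which(zi > 1e-12 & ok_pos[[i]])
        if (!length(use)) next
        m <- site_idx[[i]]
        for (j in seq_len(width)) {
          b <- m[use, j]
          cnt[, j] <- cnt[, j] +
            vapply(1:4, function(k) sum(zi[use][b == k]), numeric(1))
        }
      }
      theta <- sweep(cnt, 2, colSums(cnt), "/")
      gamma <- min(max(tot_z / n_win, 1e-3), 1 - 1e-3)
      if (ll - ll_old < tol && iter > 1L) break
      ll_old <- ll
    }
    list(theta = theta, gamma = gamma, loglik = ll, z = z)
  }

  # phase-shift move: EM can lock onto a laterally shifted alignment, a
  # well-known local optimum; re-seed from the shifted MAP sites and keep
  # the shift whose re-run likelihood is best.
  refine_shifts <- function(fit, shifts = -3:3) {
    offs <- vapply(fit$z, function(zi) which.max(zi), integer(1))
    best <- fit
    for (s in setdiff(shifts, 0L)) {
      theta <- matrix(0.25, 4, width)
      n_used <- 0L
      for (i in seq_len(n_win)) {
        o <- offs[i] + s
        if (o < 1L || o > nrow(site_idx[[i]])) next
        b <- site_idx[[i]][o, ]
        if (any(is.na(b))) next
        theta[cbind(b, seq_len(width))] <- theta[cbind(b, seq_len(width))] + 1
        n_used <- n_used + 1L
      }
      if (n_used < n_win / 2) next
      theta <- sweep(theta, 2, colSums(theta), "/")
      cand <- run_em(theta)
      if (cand$loglik > best$loglik) best <- cand
    }
    best
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      i <- sample.int(n_win, 1L)
      o <- sample.int(nrow(site_idx[[i]]), 1L)
      seed_site <- site_idx[[i]][o, ]
      theta <- matrix(0.1, 4, width)
      for (j in seq_len(width)) {
        if (!is.na(seed_site[j])) theta[seed_site[j], j] <- 0.7
      }
      theta <- sweep(theta, 2, colSums(theta), "/")
      fit <- run_em(theta)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best <- refine_shifts(best)
    # maximum-posterior site per window
    sites <- do.call(rbind, lapply(seq_len(n_win), function(i) {
      zi <- best$z[[i]]
      if (sum(zi) < 0.5) return(NULL)   # window more likely site-free
      o <- which.max(zi)
      data.frame(window = i, offset = o - 1L,
                 sequence = substr(windows[i], o, o + width - 1L),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(sites) || nrow(sites) < 2L) {
      stop("motif discovery failed: no windows carry a confident site")
    }
    pwm <- build_pwm(sites$sequence, pseudocount = 1, background = bg)
    pwm$sites <- sites
    pwm$loglik <- best$loglik
    pwm$threshold <- training_threshold(pwm, sites$sequence)
    pwm
  })
}
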