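# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# IUPAC codes for unordered base pairs, keyed by the sorted pair.
IUPAC_PAIRS <- c(
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M"
)

IUPAC_MATCH <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Sequence string -> integer vector in 1..4 (A,C,G,T); N and other IUPAC
# letters become NA so they can never match a PWM column.
seq_to_int <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
}

int_to_seq <- function(x) {
  paste(BASES[x], collapse = "")
}

# Sample one concrete sequence from an IUPAC pattern (used to plant
# consensus-derived sites).
sample_iupac <- function(pattern, n = 1) {
  letters <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  vapply(seq_len(n), function(i) {
    paste(vapply(letters, function(ch) {
      opts <- IUPAC_MATCH[[ch]]
      if (is.null(opts)) stop("unknown IUPAC code: ", ch)
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1)), collapse = "")
  }, character(1))
}

matches_iupac <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (length(s) != length(p)) return(FALSE)
  all(mapply(function(b, ch) b %in% IUPAC_MATCH[[ch]], s, p))
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Substring by 0-based half-open coordinates (the package-wide convention).
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

`subseq0<-` <- function(seq, start, end, value) {
  stopifnot(nchar(value) == end - start)
  substr(seq, start + 1L, end) <- value
  seq
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x)) stop(name, " must be a non-missing scalar")
  invisible(x)
}
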