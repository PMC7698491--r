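# TMM/GeTMM normalization, region quantification, the exact NB test and
# temporal classes.

make_cm <- function(counts, lengths = NULL, tps = NULL) {
  if (is.null(lengths)) lengths <- setNames(rep(1000, nrow(counts)),
                                            rownames(counts))
  if (is.null(tps)) tps <- rep("t5", ncol(counts))
  count_matrix(counts, lengths,
               data.frame(timepoint = tps,
                          replicate = ave(seq_along(tps), tps, FUN = seq_along)))
}

test_that("TMM factor: identity, scale invariance, oracle and edgeR", {
  set.seed(21)
  ref <- rnbinom(200, mu = runif(200, 10, 500), size = 5) + 1
  expect_equal(tmm_factor(ref, ref), 1)
  expect_equal(tmm_factor(2 * ref, ref), 1, tolerance = 1e-12)
  for (r in 1:10) {
    obs <- rnbinom(200, mu = runif(200, 10, 500), size = 5)
    obs[sample(200, 5)] <- obs[sample(200, 5)] * 10
    expect_equal(tmm_factor(obs, ref), oracle_tmm(obs, ref),
                 tolerance = 1e-10)
    # edgeR as independent cross-check (it rescales pairs to geometric
    # mean 1)
    m <- cbind(ref, obs)
    rownames(m) <- paste0("g", 1:200)
    er <- edgeR::calcNormFactors(m, refColumn = 1)[2]
    mine <- tmm_factor(obs, ref)
    expect_equal(mine / exp(mean(log(c(1, mine)))), unname(er),
                 tolerance = 1e-10)
  }
  # reciprocal symmetry after geometric-mean rescaling
  obs <- rnbinom(200, mu = runif(200, 10, 500), size = 5) + 1
  f <- tmm_factors(cbind(a = ref, b = obs))
  expect_equal(f[1] * f[2], 1, tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("GeTMM corrects for length and matches the oracle", {
  cnt <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  g <- getmm(make_cm(cnt, c(a = 1000, b = 2000)))
  expect_equal(g$values["a", 1] / g$values["b", 1], 2)
  # equal lengths: proportional to plain TMM-CPM
  set.seed(22)
  cnt2 <- matrix(rnbinom(300, mu = 100, size = 5), 100, 3,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  g2 <- getmm(make_cm(cnt2))
  cpm_ratio <- g2$values / (sweep(cnt2, 2, colSums(cnt2) * g2$factors, "/") * 1e6)
  expect_true(all(abs(cpm_ratio - 1) < 1e-12))
  # random matrices equal the from-scratch oracle to 1e-10
  for (r in 1:5) {
    n <- 80
    cnt3 <- matrix(rnbinom(n * 4, mu = runif(n, 5, 400), size = 3) + 1, n, 4,
                   dimnames = list(paste0("g", 1:n), paste0("s", 1:4)))
    len <- setNames(sample(200:3000, n), rownames(cnt3))
    g3 <- getmm(make_cm(cnt3, len))
    expect_equal(g3$values, oracle_getmm(cnt3, len), tolerance = 1e-10)
  }
  expect_error(make_cm(cnt, c(a = 0, b = 100)), "positive length")
})

test_that("region fraction is the regions' share of normalized values", {
  v <- matrix(c(2.2, 8.4, 89.4), 3, 1,
              dimnames = list(c("lnc1", "lnc2", "rest"), "s"))
  expect_equal(region_fraction(v, c("lnc1", "lnc2")), 10.6)
  expect_equal(region_fraction(v, "rest"), 89.4)
  v0 <- matrix(c(0, 100), 2, 1, dimnames = list(c("r", "g"), "s"))
  expect_equal(region_fraction(v0, "r"), 0)
  expect_equal(region_fraction(v0, "g"), 100)
  expect_error(region_fraction(v, "nope"), "unknown region")
})

test_that("BH adjustment equals the cumulative-minimum oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(23)
  for (r in 1:10) {
    p <- runif(sample(5:200, 1))
    adj <- p.adjust(p, "BH")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p order
  }
})

test_that("identical groups give logFC 0 and no significance", {
  set.seed(24)
  base <- rnbinom(60, mu = 200, size = 10)
  cnt <- matrix(rep(base, 6), 60, 6,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:6)))
  cm <- make_cm(cnt, tps = rep(c("a", "b"), each = 3))
  d <- differential(cm, "a", "b")
  expect_true(all(abs(d$logFC) < 1e-9))
  expect_true(all(d$pvalue > 1 - 1e-9))
  expect_false(any(d$significant))
  expect_error(differential(cm, "a", "nope"), "empty group")
})

test_that("the exact NB test is calibrated and powered", {
  # null: empirical flag rate at FDR 0.01 stays below 0.02
  set.seed(25)
  flagged <- 0; total <- 0
  for (r in 1:60) {
    mu <- runif(80, 20, 300)
    cnt <- matrix(rnbinom(80 * 6, mu = rep(mu, 6), size = 20), 80, 6,
                  dimnames = list(paste0("g", 1:80), paste0("s", 1:6)))
    d <- differential(make_cm(cnt, tps = rep(c("a", "b"), each = 3)), "a", "b")
    flagged <- flagged + sum(d$significant, na.rm = TRUE)
    total <- total + 80
  }
  expect_lte(flagged / total, 0.02)
  # power: a 4-fold induced gene at n = 3, dispersion 0.05
  set.seed(26)
  hits <- 0
  for (r in 1:60) {
    mu <- runif(40, 50, 300)
    cnt <- cbind(matrix(rnbinom(40 * 3, mu = rep(mu, 3), size = 20), 40, 3),
                 matrix(rnbinom(40 * 3, mu = rep(mu * c(4, rep(1, 39)), 3),
                                size = 20), 40, 3))
    rownames(cnt) <- paste0("g", 1:40); colnames(cnt) <- paste0("s", 1:6)
    d <- differential(make_cm(cnt, tps = rep(c("a", "b"), each = 3)), "b", "a")
    hits <- hits + (d$significant[1] && d$logFC[1] > 0)
  }
  expect_gte(hits / 60, 0.9)
})

test_that("temporal classes follow expression floor and significance", {
  set.seed(27)
  # gene A steadily expressed, gene B silent then induced, gene C silent
  mk <- function(m5, m15, m30) {
    c(rnbinom(3, mu = m5, size = 50), rnbinom(3, mu = m15, size = 50),
      rnbinom(3, mu = m30, size = 50))
  }
  cnt <- rbind(A = mk(500, 500, 600), B = mk(2, 4, 800), C = mk(0, 0, 0),
               D = mk(300, 300, 300), E = mk(400, 420, 380))
  colnames(cnt) <- paste0(rep(c("t5", "t15", "t30"), each = 3), "_r", 1:3)
  cm <- make_cm(cnt, tps = rep(c("t5", "t15", "t30"), each = 3))
  norm <- getmm(cm)
  d <- differential(cm, "t30", c("t5", "t15"))
  cls <- temporal_profile(norm, d)
  expect_equal(unname(cls["A"]), "early-expressed")
  expect_equal(unname(cls["B"]), "late-expressed")
  expect_equal(unname(cls["D"]), "early-expressed")
  expect_equal(unname(cls["E"]), "early-expressed")
})
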