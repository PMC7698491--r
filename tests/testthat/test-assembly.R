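# TU assembly walk, class rules, orphan handling and the landscape report.

mk_orfs <- function(...) {
  d <- data.frame(...)
  d$id <- paste0("o", seq_len(nrow(d)))
  d
}

test_that("a promoter, three ORFs and a terminator make one TU", {
  orfs <- mk_orfs(start = c(100, 500, 900), end = c(400, 800, 1200),
                  strand = "+")
  prom <- data.frame(id = "p1", tss = 50, strand = "+", class = "early",
                     active = TRUE)
  term <- data.frame(position = 1300, strand = "+", readthrough = 0.1)
  res <- assemble_tus(orfs, prom, term, 2000)
  expect_equal(nrow(res$tus), 1L)
  expect_equal(res$tus$n_orfs, 3L)
  expect_equal(res$tus$class, "early")
  expect_equal(unname(res$orf_assignment), rep(res$tus$id, 3))
})

test_that("an internal late promoter makes the TU dual-class", {
  orfs <- mk_orfs(start = c(100, 500), end = c(400, 800), strand = "+")
  prom <- data.frame(id = c("p1", "pL1"), tss = c(50, 470), strand = "+",
                     class = c("early", "late"), active = TRUE)
  term <- data.frame(position = 900, strand = "+", readthrough = 0.1)
  res <- assemble_tus(orfs, prom, term, 2000)
  expect_equal(nrow(res$tus), 1L)
  expect_equal(res$tus$class, "both")
  expect_equal(res$tus$n_promoters, 2L)
})

test_that("a leaky terminator merges the blocks it fails to close", {
  orfs <- mk_orfs(start = c(100, 600), end = c(400, 900), strand = "+")
  prom <- data.frame(id = "p1", tss = 50, strand = "+", class = "early",
                     active = TRUE)
  terms <- data.frame(position = c(500, 1000), strand = "+",
                      readthrough = c(0.9, 0.1))
  res <- assemble_tus(orfs, prom, terms, 2000)
  expect_equal(nrow(res$tus), 1L)
  expect_equal(res$tus$n_orfs, 2L)
  expect_equal(res$tus$n_terminators, 2L)   # leaky one recorded inside
  # tightening the terminator splits the second block off (no promoter
  # there, so its ORF stays unassigned)
  terms$readthrough[1] <- 0.2
  res2 <- assemble_tus(orfs, prom, terms, 2000)
  expect_equal(nrow(res2$tus), 1L)
  expect_equal(res2$tus$n_orfs, 1L)
  expect_true(is.na(res2$orf_assignment["o2"]))
})

test_that("promoters with no ORF before the terminator are orphans", {
  orfs <- mk_orfs(start = 1000, end = 1300, strand = "+")
  prom <- data.frame(id = c("p1", "p2"), tss = c(50, 900), strand = "+",
                     class = "early", active = TRUE)
  term <- data.frame(position = c(500, 1400), strand = "+", readthrough = 0.1)
  res <- assemble_tus(orfs, prom, term, 2000)
  expect_equal(res$orphan_promoters$promoter, "p1")
  expect_equal(nrow(res$tus), 1L)
  expect_equal(res$tus$n_orfs, 1L)
})

test_that("minus-strand TUs are walked right to left", {
  orfs <- mk_orfs(start = c(500, 900), end = c(800, 1200), strand = "-")
  prom <- data.frame(id = "p1", tss = 1300, strand = "-", class = "late",
                     active = TRUE)
  term <- data.frame(position = 400, strand = "-", readthrough = 0.05)
  res <- assemble_tus(orfs, prom, term, 2000)
  expect_equal(nrow(res$tus), 1L)
  expect_equal(res$tus$n_orfs, 2L)
  expect_equal(res$tus$class, "late")
  expect_equal(res$tus$tss, 1300)
  expect_equal(res$tus$end, 400)
})

test_that("TU class rule: early/late/both and the no-promoter error", {
  expect_equal(classify_tu(c("early", "early")), "early")
  expect_equal(classify_tu("late"), "late")
  expect_equal(classify_tu(c("early", "late")), "both")
  expect_error(classify_tu(character(0)), "no promoters")
})

test_that("every ORF belongs to at most one TU (partition property)", {
  d <- small_dataset(seed = 161L, n_tus = 6L)
  res <- infer_landscape(d$genome, d$arch$orfs, d$tracks,
                         d$params$timepoints, seed = 3)
  assign <- res$landscape$orf_assignment
  expect_equal(length(assign), nrow(d$arch$orfs))
  expect_setequal(names(assign), d$arch$orfs$id)
  # counts by class partition the TU set
  rep <- res$report
  expect_equal(sum(rep$by_class$n), rep$n_tus)
  expect_equal(sum(rep$by_strand$n), rep$n_tus)
})

test_that("landscape percentages are rounded to one decimal", {
  tus <- data.frame(id = sprintf("TU%02d", 1:35),
                    strand = rep(c("+", "-"), c(20, 15)),
                    class = rep(c("early", "late", "both"), c(26, 4, 5)),
                    tss = 1:35, end = 2:36, n_orfs = 1L, n_promoters = 1L,
                    n_terminators = 1L)
  fake <- list(tus = tus,
               orf_assignment = setNames(tus$id, paste0("o", 1:35)))
  rep <- landscape_report(fake)
  expect_equal(rep$by_strand$percent[rep$by_strand$level == "+"], 57.1)
  expect_equal(rep$by_strand$percent[rep$by_strand$level == "-"], 42.9)
  expect_equal(rep$by_class$n, c(26L, 4L, 5L))
  expect_equal(rep$by_class$percent, c(74.3, 11.4, 14.3))
})

test_that("the landscape is mirror-symmetric under genome reversal", {
  d <- small_dataset(seed = 171L, n_tus = 5L)
  L <- d$params$genome_length
  res <- infer_landscape(d$genome, d$arch$orfs, d$tracks,
                         d$params$timepoints, seed = 3)
  # mirror all inputs
  g_m <- genome_record("m", reverse_complement(d$genome$sequence))
  orfs_m <- d$arch$orfs
  orfs_m$start <- L - d$arch$orfs$end
  orfs_m$end <- L - d$arch$orfs$start
  orfs_m$strand <- ifelse(d$arch$orfs$strand == "+", "-", "+")
  tracks_m <- lapply(d$tracks, function(tr) {
    coverage_track(rev(tr$depth), if (tr$strand == "+") "-" else "+",
                   tr$timepoint)
  })
  names(tracks_m) <- vapply(tracks_m, function(tr)
    paste(tr$timepoint, tr$strand, sep = "."), character(1))
  res_m <- infer_landscape(g_m, orfs_m, tracks_m, d$params$timepoints,
                           seed = 3)
  # same TU count and mirrored ORF partitions with identical classes
  expect_equal(nrow(res_m$landscape$tus), nrow(res$landscape$tus))
  part <- function(r) {
    a <- r$landscape$orf_assignment
    sets <- split(names(a)[!is.na(a)], a[!is.na(a)])
    cls <- setNames(r$landscape$tus$class, r$landscape$tus$id)
    sort(vapply(names(sets), function(tu) {
      paste0(cls[[tu]], ":", paste(sort(sets[[tu]]), collapse = ","))
    }, character(1)), method = "radix")
  }
  expect_equal(unname(part(res_m)), unname(part(res)))
})
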