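# helper: build an eval_curve tibble directly, for threshold-rule tests
fake_curve <- function(thresholds, fraction, error, total = 1000) {
  out <- tibble::tibble(
    threshold = thresholds,
    n_mapped = round(fraction * total),
    fraction_mapped = fraction,
    n_errors = round(error * fraction * total),
    error_rate = error,
    no_mapped = fraction == 0
  )
  attr(out, "total_reads") <- total
  class(out) <- c("eval_curve", class(out))
  out
}

test_that("placement correctness is the 10%-of-union criterion", {
  truth <- tibble::tibble(qname = "r", tname = "chr1", tstart = 0L, tend = 100L)
  exact <- tibble::tibble(qname = "r", tname = "chr1", tstart = 0L, tend = 100L)
  expect_true(is_correct(exact, truth))
  # intersection 5, union 200: ratio 0.025 < 0.10
  off <- tibble::tibble(qname = "r", tname = "chr1", tstart = 95L, tend = 200L)
  expect_false(is_correct(off, truth))
  other <- tibble::tibble(qname = "r", tname = "chr2", tstart = 0L, tend = 100L)
  expect_false(is_correct(other, truth))
  expect_error(
    is_correct(tibble::tibble(qname = "ghost", tname = "chr1", tstart = 0L, tend = 1L),
               truth),
    "ghost"
  )
})

test_that("is_correct agrees with brute-force intersection/union", {
  withr::with_seed(17, {
    n <- 10000
    t_start <- sample(0:150, n, replace = TRUE)
    t_end <- t_start + sample(1:50, n, replace = TRUE)
    m_start <- sample(0:150, n, replace = TRUE)
    m_end <- m_start + sample(1:50, n, replace = TRUE)
    truth <- tibble::tibble(qname = paste0("r", 1:n), tname = "c",
                            tstart = t_start, tend = t_end)
    maps <- tibble::tibble(qname = paste0("r", 1:n), tname = "c",
                           tstart = m_start, tend = m_end)
    got <- is_correct(maps, truth)
    want <- vapply(seq_len(n), function(i) {
      brute_iou(m_start[i], m_end[i], t_start[i], t_end[i]) >= 0.10
    }, TRUE)
    expect_equal(got, want)
  })
})

test_that("eval_curve computes cumulative fractions and handles edge cases", {
  truth <- tibble::tibble(qname = paste0("r", 1:4), tname = "c",
                          tstart = c(0L, 100L, 200L, 300L), tend = c(50L, 150L, 250L, 350L))
  # all four mapped correctly at mapq 60
  paf <- dplyr::mutate(truth, qlen = 50L, qstart = 0L, qend = 50L, strand = "+",
                       tlen = 400L, nmatch = 50L, alen = 50L, mapq = 60L, tp = "P")
  cv <- eval_curve(paf, truth)
  expect_equal(cv$fraction_mapped, rep(1, 7))
  expect_equal(cv$error_rate, rep(0, 7))
  expect_equal(attr(cv, "total_reads"), 4)
  # no mappings: fraction 0, error defined as 0 and flagged
  cv0 <- eval_curve(paf[0, ], truth)
  expect_equal(cv0$fraction_mapped, rep(0, 7))
  expect_equal(cv0$error_rate, rep(0, 7))
  expect_true(all(cv0$no_mapped))
  # secondary records are ignored; unmapped reads stay in the denominator
  paf2 <- paf[1:2, ]
  paf2$tp[2] <- "S"
  cv2 <- eval_curve(paf2, truth, thresholds = c(60, 0))
  expect_equal(cv2$fraction_mapped, c(0.25, 0.25))
  # one wrong placement out of two mapped
  paf3 <- paf[1:2, ]
  paf3$tstart[2] <- 300L
  paf3$tend[2] <- 350L
  paf3$mapq[2] <- 10L
  cv3 <- eval_curve(paf3, truth, thresholds = c(60, 0))
  expect_equal(cv3$n_mapped, c(1L, 2L))
  expect_equal(cv3$error_rate, c(0, 0.5))
})

test_that("curves from low-mapq-concentrated errors are monotone in threshold", {
  withr::with_seed(19, {
    truth <- tibble::tibble(
      qname = sprintf("r%04d", 1:2000), tname = "c",
      tstart = as.integer(seq(0, 199900, length.out = 2000)),
      tend = as.integer(seq(0, 199900, length.out = 2000)) + 100L
    )
    paf <- synth_mappings(truth, c(c = 200000L), wrong_rate = 0.1,
                          mapq_model = mapq_confidence(), seed = 23)
    cv <- eval_curve(paf, truth, thresholds = 60:0)
    expect_true(all(diff(cv$fraction_mapped) >= 0)) # rises as t drops
    expect_true(all(diff(rev(cv$error_rate)) <= 1e-12 + 0)) # error falls as t rises
  })
})

test_that("respective_threshold picks the highest strictly dominating threshold", {
  th <- 0:60
  dominating <- fake_curve(th, fraction = rep(0.95, 61), error = rep(0.001, 61))
  expect_equal(respective_threshold(dominating, 0.93, 0.002), 60)
  never <- fake_curve(th, fraction = rep(0.90, 61), error = rep(0.01, 61))
  expect_true(is.na(respective_threshold(never, 0.93, 0.002)))
  # dominates only at thresholds <= 50
  frac <- ifelse(th <= 50, 0.95, 0.91)
  err <- ifelse(th <= 50, 0.001, 0.003)
  mixed <- fake_curve(th, frac, err)
  expect_equal(respective_threshold(mixed, 0.93, 0.002), 50)
  # ties lose: equality on either axis does not qualify
  tied <- fake_curve(th, fraction = rep(0.93, 61), error = rep(0.001, 61))
  expect_true(is.na(respective_threshold(tied, 0.93, 0.002)))
  # the returned threshold always satisfies both strict inequalities
  rt <- respective_threshold(mixed, 0.93, 0.002)
  at <- mixed[mixed$threshold == rt, ]
  expect_gt(at$fraction_mapped, 0.93)
  expect_lt(at$error_rate, 0.002)
})

test_that("percent_better counts thresholds 1..60 over a denominator of 60", {
  th <- 0:60
  dominating <- fake_curve(th, rep(0.95, 61), rep(0.001, 61))
  expect_equal(percent_better(dominating, 0.93, 0.002), 1)
  never <- fake_curve(th, rep(0.90, 61), rep(0.01, 61))
  expect_equal(percent_better(never, 0.93, 0.002), 0)
  # dominating at exactly 20 thresholds (41..60)
  frac <- ifelse(th >= 41, 0.95, 0.90)
  err <- ifelse(th >= 41, 0.001, 0.01)
  expect_equal(percent_better(fake_curve(th, frac, err), 0.93, 0.002), 20 / 60)
  # threshold 0 is excluded from the count
  frac0 <- ifelse(th == 0, 0.95, 0.90)
  err0 <- ifelse(th == 0, 0.001, 0.01)
  expect_equal(percent_better(fake_curve(th, frac0, err0), 0.93, 0.002), 0)
  expect_error(percent_better(fake_curve(0:30, rep(0.9, 31), rep(0.1, 31)), 0.93, 0.002),
               "1\\.\\.60")
})

test_that("select_msrs ranks three criteria and flags best-in-category", {
  th <- 0:60
  hpc <- fake_curve(th, fraction = seq(1, 0.93, length.out = 61),
                    error = seq(0.05, 0.002, length.out = 61))
  curves <- list()
  withr::with_seed(29, {
    for (i in 1:50) {
      # mediocre curves: never dominate the reference
      curves[[sprintf("c%03d", i)]] <-
        fake_curve(th, rep(0.90, 61), rep(0.01, 61))
    }
  })
  # one strictly dominant curve
  curves[["winner"]] <- fake_curve(th, rep(0.99, 61), rep(1e-4, 61))
  sel <- select_msrs(curves, hpc)
  expect_equal(sel$union, "winner")
  expect_true(all(sel$best == "winner"))
  expect_equal(nrow(sel$top_fraction), 1)
  # all candidates identical to the reference: nothing qualifies
  sel2 <- select_msrs(list(a = hpc, b = hpc), hpc)
  expect_equal(length(sel2$union), 0)
  expect_equal(nrow(sel2$top_error), 0)
  # union of three top-20 lists can never exceed 60
  many <- c(curves, stats::setNames(
    lapply(1:80, function(i) fake_curve(th, rep(0.94 + i * 1e-4, 61),
                                        rep(0.0015 - i * 1e-6, 61))),
    sprintf("d%03d", 1:80)
  ))
  sel3 <- select_msrs(many, hpc)
  expect_lte(length(sel3$union), 60)
  expect_equal(nrow(sel3$top_fraction), 20)
  # tidy/glance expose membership flags and counts
  td <- tidy(sel3)
  expect_true(all(c("in_top_fraction", "in_top_error", "in_top_percent", "selected")
                  %in% names(td)))
  expect_equal(sum(td$selected), length(sel3$union))
  gl <- glance(sel3)
  expect_equal(gl$n_candidates, length(many))
})

test_that("selection tie-breaks are deterministic by id", {
  th <- 0:60
  hpc <- fake_curve(th, rep(0.93, 61), rep(0.002, 61))
  same <- fake_curve(th, rep(0.95, 61), rep(0.001, 61))
  sel <- select_msrs(list(zz = same, aa = same, mm = same), hpc)
  expect_equal(sel$top_fraction$id, c("aa", "mm", "zz"))
  expect_equal(sel$best[["best_fraction"]], "aa")
})

test_that("repeat filter keeps reads with majority repeat overlap", {
  truths <- tibble::tibble(
    qname = c("inside", "partial40", "partial60", "outside"),
    tname = "chr1",
    tstart = c(100L, 180L, 160L, 500L),
    tend = c(200L, 280L, 260L, 600L)
  )
  repeats <- tibble::tibble(chrom = "chr1", start = 50L, end = 220L)
  kept <- repeat_read_filter(truths, repeats)
  # inside: 100% overlap; partial40: 40/100; partial60: 60/100
  expect_setequal(kept$qname, c("inside", "partial60"))
  # empty repeat set: nothing survives
  expect_equal(nrow(repeat_read_filter(truths, repeats[0, ])), 0)
  # exactly 50% is not strictly greater than half
  half <- tibble::tibble(qname = "half", tname = "chr1", tstart = 170L, tend = 270L)
  expect_equal(nrow(repeat_read_filter(half, repeats)), 0)
  # overlap accumulates across multiple repeat intervals
  split_reps <- tibble::tibble(chrom = "chr1", start = c(100L, 160L), end = c(130L, 190L))
  read <- tibble::tibble(qname = "r", tname = "chr1", tstart = 100L, tend = 200L)
  expect_equal(nrow(repeat_read_filter(read, split_reps)), 1)
})

test_that("autoplot produces ggplot objects for curves and selections", {
  th <- 0:60
  cv <- fake_curve(th, seq(1, 0.9, length.out = 61), seq(0.05, 0.001, length.out = 61))
  expect_s3_class(autoplot(cv), "ggplot")
  sel <- select_msrs(list(a = cv, b = fake_curve(th, rep(0.99, 61), rep(1e-4, 61))),
                     cv)
  expect_s3_class(autoplot(sel), "ggplot")
  expect_s3_class(glance(cv), "tbl_df")
})
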