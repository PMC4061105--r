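test_that("quality profile matches the per-equation oracle", {
  C <- blosum20()
  for (seed in 1:20) {
    set.seed(seed)
    M <- sample(2:8, 1); N <- sample(2:12, 1)
    mat <- matrix(sample(c(hmmdissect::HMM_ALPHABET, "-"), M * N,
                         replace = TRUE, prob = c(rep(1, 20), 3)),
                  M, N)
    aln <- msa(apply(mat, 1, paste, collapse = ""))
    qp <- quality_profile(aln)
    ora <- oracle_quality(aln$mat, C)
    expect_equal(qp$Q, ora$Q, tolerance = 1e-9)
    expect_equal(qp$Q_hat, ora$Q_hat, tolerance = 1e-9)
    expect_equal(qp$Q_tilde, ora$Q_tilde, tolerance = 1e-9)
    # bounds and argmin property
    expect_true(all(qp$Q_hat >= 0 & qp$Q_hat <= 1))
    if (max(qp$Q) > min(qp$Q))
      expect_equal(qp$Q_hat[which.min(qp$Q)], 1)
  }
})

test_that("degenerate and gap columns behave as documented", {
  # all-identical columns: max Q == min Q, every Q_hat forced to 1
  aln <- msa(c("AAAA", "AAAA", "AAAA"))
  qp <- quality_profile(aln)
  expect_equal(qp$Q_hat, rep(1, 4))
  expect_equal(qp$Q_tilde, rep(1, 4))
  # an entirely gapped column contributes k = 0, hence Q_tilde = 0
  aln2 <- msa(c("A-A", "A-C", "A-A"))
  qp2 <- quality_profile(aln2)
  expect_equal(qp2$k[2], 0L)
  expect_equal(qp2$Q_tilde[2], 0)
  expect_error(quality_profile(msa("AXZ")), "X|Z")
})

test_that("minimum-sequence binomial tail is exact", {
  expect_equal(min_sequence_pvalue(4, 4), 0.0625)
  expect_equal(min_sequence_pvalue(3, 3), 0.125)
  expect_equal(min_sequence_pvalue(2, 2), 0.25)
  expect_equal(min_sequence_pvalue(1, 1), 0.5)
  expect_equal(min_sequence_pvalue(6, 0), 1)
  for (M in c(3, 7, 12)) for (k in c(0, 1, M %/% 2, M))
    expect_equal(min_sequence_pvalue(M, k), oracle_binom_tail(M, k),
                 tolerance = 1e-12)
  expect_error(min_sequence_pvalue(3, 4), "k <= M")
})

test_that("quality segmentation thresholds and intervals", {
  seg <- segment_by_quality(c(0.9, 0.9, 0.01, 0.9), cutoff = 0.06)
  expect_equal(seg$classes, c("FOLD", "FOLD", "REMNANT", "FOLD"))
  expect_equal(seg$intervals$start, c(1L, 3L, 4L))
  expect_equal(seg$intervals$end, c(2L, 3L, 4L))
  expect_equal(seg$intervals$class, c("FOLD", "REMNANT", "FOLD"))
  # boundary cutoffs
  expect_equal(segment_by_quality(runif(5), cutoff = 0)$classes,
               rep("FOLD", 5))
  all_in <- segment_by_quality(rep(0.5, 7), cutoff = 0.2)
  expect_equal(nrow(all_in$intervals), 1L)
  expect_equal(all_in$intervals$end, 7L)
  expect_error(segment_by_quality(c(0.1, 0.2), cutoff = 0.5,
                                  model_length = 3), "length")
})

test_that("raising the cutoff never grows the FOLD set", {
  set.seed(42)
  qt <- runif(50)
  prev <- rep(TRUE, 50)
  for (cut in seq(0, 1, by = 0.05)) {
    fold <- segment_by_quality(qt, cut)$classes == "FOLD"
    expect_true(all(fold <= prev))   # set inclusion
    prev <- fold
  }
})

test_that("DSSP segmentation separates structural from loop/gap", {
  expect_equal(segment_by_dssp(rep("H", 5))$intervals$class, "FOLD")
  seg <- segment_by_dssp(c("H", "H", " ", "T", "-"))
  expect_equal(seg$classes,
               c("FOLD", "FOLD", "REMNANT", "FOLD", "REMNANT"))
  expect_equal(segment_by_dssp(rep(" ", 4))$intervals$class, "REMNANT")
  expect_error(segment_by_dssp(c("H", "Q")), "unknown")
})

test_that("SEG column probability follows the two-branch rule", {
  # k = 0: tail is 1, no rejection, floor probability
  p0 <- seg_column_probability(rep(0, 6))
  expect_equal(p0$p_value, 1)
  expect_equal(p0$k_exp, 0)
  expect_equal(p0$p_exp, 0.01)
  expect_false(p0$high_complexity)
  # M = 4, k = 4: tail 0.0625 misses alpha = 0.05, same branch
  p4 <- seg_column_probability(rep(1, 4))
  expect_equal(p4$p_value, 0.0625)
  expect_equal(p4$p_exp, 0.01)
  # M = 8, k = 8: tail 1/256 rejects; literal product rule
  p8 <- seg_column_probability(rep(1, 8))
  expect_equal(p8$p_value, 1 / 256)
  expect_equal(p8$k_exp, 8 / 256)
  expect_equal(p8$p_exp, (8 / 256) / 8)
  expect_false(p8$high_complexity)       # the literal form stays < 0.8
  # complement variant: k_exp = (1 - P) * k
  p8c <- seg_column_probability(rep(1, 8), complement = TRUE)
  expect_equal(p8c$k_exp, (1 - 1 / 256) * 8)
  expect_equal(p8c$p_exp, (1 - 1 / 256))
  expect_true(p8c$high_complexity)
  # shrinking alpha never moves a column into the rejection branch
  for (k in 0:8) {
    reject_10 <- seg_column_probability(rep(c(1, 0), c(k, 8 - k)),
                                        alpha = 0.10)$k_exp > 0
    reject_01 <- seg_column_probability(rep(c(1, 0), c(k, 8 - k)),
                                        alpha = 0.01)$k_exp > 0
    expect_true(reject_01 <= reject_10)
  }
  expect_error(seg_column_probability(numeric(0)), "empty")
})

test_that("mask-level SEG segmentation emits tiling intervals", {
  mask <- rbind(matrix(1, 9, 4), matrix(0, 0, 4))
  mask <- cbind(mask, matrix(0, 9, 3))       # 4 high + 3 low columns
  seg <- segment_by_seg(mask, complement = TRUE)
  expect_equal(seg$classes, rep(c("FOLD", "REMNANT"), c(4, 3)))
  expect_equal(sum(seg$intervals$end - seg$intervals$start + 1),
               seg$length)
})

test_that("cutoff calibration tabulates confusion counts and rates", {
  ge5 <- c(0.9, 0.8, 0.2, 0.7)
  lt5 <- c(0.1, 0.05, 0.6)
  tab <- calibrate_cutoff(ge5, lt5, grid = c(0.5))
  expect_equal(tab$TP, 3); expect_equal(tab$FN, 1)
  expect_equal(tab$FP, 1); expect_equal(tab$TN, 2)
  expect_equal(tab$TPR, 0.75); expect_equal(tab$FPR, 1 / 3)
  # FPR is 0 whenever FP is 0, at any TN
  expect_equal(confusion_rates(5, 5, 0, 123)$FPR, 0)
  # rates non-increasing in the cutoff
  set.seed(7)
  tab2 <- calibrate_cutoff(runif(500), runif(300)^2)
  expect_true(all(diff(tab2$TPR) <= 0))
  expect_true(all(diff(tab2$FPR) <= 0))
  expect_error(calibrate_cutoff(numeric(0), lt5), "non-empty")
})
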