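test_that("hand-summed scores reproduce: K = 2 and K = 4 fixtures", {
  # K = 2: emissions 1.0, 2.0; B->M1 0.5; M1->M2 0.25; M2->E 0; f = -0.25
  me <- matrix(0, 2, 20); me[1, 1] <- 1.0; me[2, 2] <- 2.0
  ie <- matrix(-0.5, 2, 20); ie[2, ] <- -Inf
  tr <- matrix(-Inf, 2, 9, dimnames = list(NULL, HMM_TRANSITIONS))
  tr[1, "MM"] <- 0.25; tr[1, "BM"] <- 0.5; tr[2, "ME"] <- 0
  m2 <- hmm_model("k2", me, ie, tr,
                  xt = setNames(c(-0.25, rep(0, 7)), HMM_XT_NAMES),
                  nult = c(0, 0), nule = rep(0, 20),
                  evd_mu = 0, evd_lambda = 0.5)
  p <- match_path(c("A", "C"))
  expect_equal(reconstruct_score(p, m2), 3.5)
  # empty path scores the fixed score alone
  empty <- alignment_path(
    data.frame(fragment = integer(0), state = character(0),
               model_pos = integer(0), seq_pos = integer(0)),
    hit_id = "none")
  expect_equal(reconstruct_score(empty, m2), -0.25)
  # K = 4 hand model, full match path on the diagonal residues
  hm <- hand_model()
  p4 <- match_path(c("A", "C", "D", "E"))
  expect_equal(reconstruct_score(p4, hm), 3.875)
})

test_that("-Inf sentinel propagates through emissions", {
  hm <- hand_model()
  hm$match_emission[2, "A"] <- -Inf
  p <- match_path(c("A", "A", "D", "E"))
  expect_equal(reconstruct_score(p, hm), -Inf)
})

test_that("production scorer equals the naive oracle on random paths", {
  for (seed in 1:25) {
    model <- make_model(K = sample(3:15, 1), seed = seed)
    fx <- make_alignment_with_truth(model, seed = seed + 1000,
                                    p_delete = 0.2, p_insert = 0.2)
    expect_equal(reconstruct_score(fx$path, model), fx$hand_score,
                 tolerance = 1e-12)
  }
})

test_that("Gumbel E-value closed forms, limits and monotonicity", {
  m <- make_model(K = 3, seed = 1)
  m$evd_mu <- 0; m$evd_lambda <- 0.7
  N <- 540261
  # at v = mu the survival is 1 - exp(-1)
  expect_equal(evalue(0, m, N), N * (1 - exp(-1)), tolerance = 1e-12)
  # frozen high-precision reference for mu=0, lambda=0.7, v=10
  expect_equal(evalue(10, m, N), 492.429709584258582, tolerance = 1e-12)
  expect_equal(evalue(1e6, m, N), 0)
  expect_equal(evalue(-1e6, m, N), N)
  # deep tail keeps the asymptotic form instead of underflowing
  expect_gt(evalue(900, m, N), 0)
  v <- seq(-50, 120, by = 0.5)
  expect_true(all(diff(evalue(v, m, N)) <= 0))   # saturates at N far left
  expect_true(all(diff(evalue(seq(0, 60, 0.5), m, N)) < 0))
  expect_true(all(evalue(v, m, 1000) < evalue(v, m, 2000)))
  expect_error(evalue(1, m, db_size = N, mu = 0, lambda = -1),
               "positive")
})

test_that("dissection partitions every term and conserves the total", {
  hm <- hand_model()
  p4 <- match_path(c("A", "C", "D", "E"))
  seg <- segmentation(rep(c("FOLD", "REMNANT"), each = 2))
  d <- dissect(p4, hm, seg)
  # hand-partitioned sums: fold gets B->M1, e1, M1->M2, e2
  expect_equal(d$fold_score, 0.5 + 1.0 + 0.25 + 2.0)
  expect_equal(d$remnant_score, -0.125 + 0.5 - 0.25 + 0.25 + 0)
  expect_equal(d$fold_score + d$remnant_score + d$fixed, d$total_score)
  # all-FOLD segmentation puts everything but f into the fold sum
  d_all <- dissect(p4, hm, segmentation(rep("FOLD", 4)))
  expect_equal(d_all$fold_score, d_all$total_score - d_all$fixed)
  expect_equal(d_all$remnant_score, 0)
  expect_error(dissect(p4, hm, segmentation(rep("FOLD", 3))), "positions")
})

test_that("conservation and refinement invariance on random fixtures", {
  for (seed in 1:10) {
    model <- make_model(K = 10, seed = seed)
    fx <- make_alignment_with_truth(model, seed = seed + 50,
                                    p_delete = 0.15, p_insert = 0.15)
    cl <- sample(c("FOLD", "REMNANT"), 10, replace = TRUE)
    d <- dissect(fx$path, model, segmentation(cl))
    expect_equal(d$fold_score + d$remnant_score + d$fixed,
                 d$total_score, tolerance = 1e-12)
    # merging all classes reproduces the plain reconstruction
    expect_equal(d$total_score, reconstruct_score(fx$path, model),
                 tolerance = 1e-12)
    # scores depend only on the per-position classes, so any interval
    # refinement (same classes) gives identical sums by construction;
    # flipping one position must change the partition but not the total
    cl2 <- cl; cl2[4] <- setdiff(c("FOLD", "REMNANT"), cl[4])
    d2 <- dissect(fx$path, model, segmentation(cl2))
    expect_equal(d2$total_score, d$total_score, tolerance = 1e-12)
  }
})

test_that("multi-fragment hits sum per class before E-values", {
  model <- make_model(K = 8, seed = 9, local_entry = TRUE)
  steps <- data.frame(
    fragment = rep(c(1L, 2L), each = 3),
    state = rep("M", 6),
    model_pos = c(1:3, 6:8),
    seq_pos = c(1:3, 21:23))
  p <- alignment_path(steps, hit_id = "frag")
  p$residue <- rep("A", 6)
  seg <- segmentation(rep(c("FOLD", "REMNANT"), each = 4))
  d <- dissect(p, model, seg)
  expect_length(d$fragment_scores, 2L)
  expect_equal(d$fold_score + d$remnant_score + d$fixed, d$total_score)
  expect_equal(sum(d$fragment_scores) + d$fixed, d$total_score,
               tolerance = 1e-12)
})

test_that("E-value ratio and verdict bands", {
  expect_equal(evalue_ratio(7.6e-1, 6.7e-6), 7.6e-1 / 6.7e-6)
  expect_equal(evalue_ratio(1, 1), 1)
  expect_error(evalue_ratio(1, 0), "positive")
  expect_equal(ratio_verdict(c(1e-5, 1, 1e5)),
               c("homology-supporting", "on-par", "spurious"))
})

test_that("dissect_hits tabulates one row per hit", {
  model <- make_model(K = 6, seed = 4)
  paths <- lapply(1:3, function(s)
    make_alignment_with_truth(model, seed = s)$path)
  seg <- segmentation(rep(c("FOLD", "REMNANT"), c(3, 3)))
  tab <- dissect_hits(paths, model, seg)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("v", "E1", "E2", "ratio", "verdict") %in% names(tab)))
  expect_equal(tab$v, tab$fold_score + tab$remnant_score + tab$f,
               tolerance = 1e-12)
})
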