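test_that("label truth table over all significance patterns", {
  S <- 0.01   # significant
  I <- 5.0    # insignificant (threshold 0.1)
  expect_equal(label_hit(S, S, I), "TP")
  expect_equal(label_hit(S, S, S), "TP")
  expect_equal(label_hit(I, I, I), "TN")
  expect_equal(label_hit(I, I, S), "TN")
  expect_equal(label_hit(S, I, S), "FP")
  expect_equal(label_hit(I, S, I), "FN")
  # the two patterns only the fixed score can produce are undefined
  expect_equal(label_hit(I, S, S), "UNDEF")
  expect_equal(label_hit(S, I, I), "UNDEF")
  # thresholds are inclusive and configurable
  expect_equal(label_hit(0.1, 0.1, 0.2), "TP")
  expect_equal(label_hit(0.2, 0.2, 0.3, significance = 0.25), "TP")
})

test_that("overlap pairing, orphans and the pairing invariant", {
  mk <- function(seq_id, start, end, label)
    data.frame(seq_id = seq_id, start = start, end = end, label = label)
  a <- mk(c("seq1", "seq1", "seq2"), c(10, 200, 5), c(80, 260, 50),
          c("TP", "TP", "TN"))
  b <- mk(c("seq1", "seq3"), c(15, 1), c(70, 40), c("FN", "TP"))
  res <- pair_hits(a, b)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$pair_class, "positive_concordance")
  expect_equal(nrow(res$orphans_a), 2L)   # seq1[200,260] and seq2
  expect_equal(nrow(res$orphans_b), 1L)   # seq3
  # 2*pairs + orphans == total hits
  expect_equal(2 * nrow(res$pairs) + nrow(res$orphans_a) +
                 nrow(res$orphans_b), nrow(a) + nrow(b))
  # same sequence, disjoint segments: two orphans
  res2 <- pair_hits(mk("seq1", 10, 80, "TP"), mk("seq1", 200, 260, "FN"))
  expect_null(res2$pairs)
  expect_equal(nrow(res2$orphans_a) + nrow(res2$orphans_b), 2L)
  # minimum overlap fraction filters marginal pairs
  res3 <- pair_hits(mk("s", 1, 100, "TP"), mk("s", 100, 199, "TP"),
                    min_overlap_frac = 0.5)
  expect_null(res3$pairs)
})

test_that("pair classes follow the 16-cell concordance table", {
  labels <- c("TP", "FN", "FP", "TN")
  for (la in labels) for (lb in labels) {
    a <- data.frame(seq_id = "s", start = 1, end = 50, label = la)
    b <- data.frame(seq_id = "s", start = 10, end = 60, label = lb)
    got <- pair_hits(a, b)$pairs$pair_class
    a_true <- la %in% c("TP", "FN")
    b_true <- lb %in% c("TP", "FN")
    want <- if (a_true && b_true) "positive_concordance"
            else if (!a_true && !b_true) "negative_concordance"
            else if (a_true) "discordance_1" else "discordance_2"
    expect_equal(got, want, info = paste(la, lb))
  }
})

test_that("greedy many-to-many resolution is deterministic", {
  a <- data.frame(seq_id = "s", start = c(1, 40), end = c(60, 100),
                  label = c("TP", "TP"))
  b <- data.frame(seq_id = "s", start = 30, end = 90, label = c("FN"))
  res <- pair_hits(a, b)
  # b overlaps both; the larger overlap ([40,90] = 51) wins
  expect_equal(res$pairs$start_a, 40)
  expect_equal(nrow(res$orphans_a), 1L)
})

test_that("domain rates: arithmetic, identity and edge cases", {
  mk_pairs <- function(combos) {
    data.frame(seq_id = paste0("s", seq_along(combos)),
               start_a = 1, end_a = 10, start_b = 1, end_b = 10,
               label_a = substr(combos, 1, 2),
               label_b = substr(combos, 3, 4),
               overlap = 10,
               pair_class = hmmdissect:::pair_class_of(substr(combos, 1, 2),
                                          substr(combos, 3, 4)))
  }
  pairs <- mk_pairs(c(rep("TPTP", 5), rep("TPFN", 2), "FNFN",
                      rep("TNTN", 3), "FPFP", rep("TPFP", 2), "TNTP"))
  r <- domain_rates(pairs)
  expect_equal(r$counts[["paired"]], 15)
  expect_equal(r$positive_concordance, 100 * 8 / 15)
  expect_equal(r$negative_concordance, 100 * 4 / 15)
  expect_equal(r$total_discordance, 100 * 3 / 15)
  expect_equal(r$positive_concordance + r$negative_concordance +
                 r$total_discordance, 100)
  expect_equal(r$fn_rate, 100 * 3 / 15)    # TPFN, TPFN, FNFN
  expect_equal(r$fp_rate, 100 * 1 / 15)    # FPFP
  # all-TPTP: perfect concordance, no error pairs
  perfect <- domain_rates(mk_pairs(rep("TPTP", 4)))
  expect_equal(perfect$positive_concordance, 100)
  expect_equal(perfect$fn_rate, 0)
  expect_equal(perfect$fp_rate, 0)
  expect_error(domain_rates(NULL), "no paired hits")
})

test_that("hit tables read from TSV are labelled on the fly", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(hit_id = c("h1", "h2"), seq_id = c("s1", "s2"),
                   start = c(1, 5), end = c(50, 80),
                   total_E = c(0.01, 5), high_E = c(0.02, 0.01),
                   low_E = c(2, 3), engine = "engineA")
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- read_hit_table(tf)
  expect_equal(hits$label, c("TP", "FN"))
})
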