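# Label hits TP/FN/FP/TN from the three E-values, pair hits across two
# search engines by shared sequence segment, and compute concordance,
# discordance and FN/FP rates.

#' Label a hit from its three E-values
#'
#' The total, high-quality (fold-critical) and low-quality (remnant)
#' E-values are each called significant at `significance` and the
#' pattern maps to a label:
#' \itemize{
#'   \item total and high-quality significant: TP (either low-quality);
#'   \item total and high-quality insignificant: TN (either low-quality);
#'   \item total significant, high-quality not, low-quality significant: FP;
#'   \item total insignificant, high-quality significant, low-quality not: FN;
#'   \item the two remaining patterns (where only the fixed score can
#'     have flipped the total): UNDEF.
#' }
#'
#' @param total_E,high_E,low_E E-values (vectorised).
#' @param significance E-value significance call, default 0.1.
#' @return character vector over `{"TP","FN","FP","TN","UNDEF"}`.
#' @export
label_hit <- function(total_E, high_E, low_E, significance = 0.1) {
  t_sig <- total_E <= significance
  h_sig <- high_E <= significance
  l_sig <- low_E <= significance
  out <- rep("UNDEF", length(t_sig))
  out[t_sig & h_sig] <- "TP"
  out[!t_sig & !h_sig] <- "TN"
  out[t_sig & !h_sig & l_sig] <- "FP"
  out[!t_sig & h_sig & !l_sig] <- "FN"
  out
}

POSITIVE_LABELS <- c("TP", "FN")   # hits the engine regards as true

pair_class_of <- function(a, b) {
  a_true <- a %in% POSITIVE_LABELS
  b_true <- b %in% POSITIVE_LABELS
  ifelse(a == "UNDEF" | b == "UNDEF", NA_character_,
  ifelse(a_true & b_true, "positive_concordance",
  ifelse(!a_true & !b_true, "negative_concordance",
  ifelse(a_true, "discordance_1", "discordance_2"))))
}

#' Pair labelled hits from two search engines
#'
#' Hits are paired when they lie on the same sequence and their segments
#' overlap by at least one position (and by at least `min_overlap_frac`
#' of the shorter segment). Many-to-many overlaps are resolved greedily:
#' candidate pairs are taken in order of decreasing overlap length, ties
#' broken on the smaller start coordinate, and each hit is used at most
#' once. Unpaired hits become orphans.
#'
#' @param hits_a,hits_b data frames with columns `seq_id`, `start`,
#'   `end`, `label` (and any others, carried through).
#' @param min_overlap_frac minimum overlap as a fraction of the shorter
#'   segment (default 0: one shared position suffices).
#' @return list with `pairs` (data frame: `seq_id`, coordinates and
#'   labels from both engines, `pair_class`), `orphans_a`, `orphans_b`.
#' @export
pair_hits <- function(hits_a, hits_b, min_overlap_frac = 0) {
  need <- c("seq_id", "start", "end", "label")
  stopifnot(all(need %in% names(hits_a)), all(need %in% names(hits_b)))
  cand <- NULL
  for (ia in seq_len(nrow(hits_a))) {
    on_seq <- which(hits_b$seq_id == hits_a$seq_id[ia])
    for (ib in on_seq) {
      ov <- min(hits_a$end[ia], hits_b$end[ib]) -
            max(hits_a$start[ia], hits_b$start[ib]) + 1L
      if (ov < 1L) next
      shorter <- min(hits_a$end[ia] - hits_a$start[ia],
                     hits_b$end[ib] - hits_b$start[ib]) + 1L
      if (ov < min_overlap_frac * shorter) next
      cand <- rbind(cand, data.frame(ia = ia, ib = ib, overlap = ov,
                                     start = max(hits_a$start[ia],
                                                 hits_b$start[ib])))
    }
  }
  used_a <- logical(nrow(hits_a)); used_b <- logical(nrow(hits_b))
  pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(-cand$overlap, cand$start, cand$ia, cand$ib), ]
    for (r in seq_len(nrow(cand))) {
      ia <- cand$ia[r]; ib <- cand$ib[r]
      if (used_a[ia] || used_b[ib]) next
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      pairs <- rbind(pairs, data.frame(
        seq_id = hits_a$seq_id[ia],
        start_a = hits_a$start[ia], end_a = hits_a$end[ia],
        start_b = hits_b$start[ib], end_b = hits_b$end[ib],
        label_a = hits_a$label[ia], label_b = hits_b$label[ib],
        overlap = cand$overlap[r]))
    }
    pairs$pair_class <- pair_class_of(pairs$label_a, pairs$label_b)
  }
  list(pairs = pairs,
       orphans_a = hits_a[!used_a, , drop = FALSE],
       orphans_b = hits_b[!used_b, , drop = FALSE])
}

#' Concordance, discordance and FN/FP rates over paired hits
#'
#' Percentages over the paired-hit count (orphans are excluded):
#' \itemize{
#'   \item positive concordance: both engines call the hit true
#'     (labels in \{TP, FN\});
#'   \item negative concordance: both call it false (\{TN, FP\});
#'   \item total discordance: the engines disagree;
#'   \item FN rate: pairs TPFN + FNTP + FNFN (obscured true homologies);
#'   \item FP rate: pairs FPTN + TNFP + FPFP (score-inflated false hits).
#' }
#' The three concordance/discordance percentages sum to exactly 100.
#'
#' @param pairs the `pairs` data frame from [pair_hits()] (UNDEF-labelled
#'   pairs, if any, are dropped with a warning).
#' @return list of percentages `positive_concordance`,
#'   `negative_concordance`, `total_discordance`, `fn_rate`, `fp_rate`,
#'   plus the backing `counts`.
#' @export
domain_rates <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs)) stop("no paired hits")
  if (anyNA(pairs$pair_class)) {
    warning("dropping ", sum(is.na(pairs$pair_class)),
            " pair(s) with UNDEF labels")
    pairs <- pairs[!is.na(pairs$pair_class), , drop = FALSE]
  }
  n <- nrow(pairs)
  combo <- paste0(pairs$label_a, pairs$label_b)
  pos <- sum(pairs$pair_class == "positive_concordance")
  neg <- sum(pairs$pair_class == "negative_concordance")
  dis <- sum(pairs$pair_class %in% c("discordance_1", "discordance_2"))
  fn <- sum(combo %in% c("TPFN", "FNTP", "FNFN"))
  fp <- sum(combo %in% c("FPTN", "TNFP", "FPFP"))
  list(positive_concordance = 100 * pos / n,
       negative_concordance = 100 * neg / n,
       total_discordance = 100 * dis / n,
       fn_rate = 100 * fn / n,
       fp_rate = 100 * fp / n,
       counts = c(paired = n, positive = pos, negative = neg,
                  discordant = dis, fn_pairs = fn, fp_pairs = fp))
}

#' Read/write labelled hit tables as TSV
#'
#' Columns `hit_id`, `seq_id`, `start`, `end`, `total_E`, `high_E`,
#' `low_E`, `engine`; a `label` column is added via [label_hit()] when
#' absent.
#' @param path file path.
#' @param significance threshold for [label_hit()].
#' @return data frame of hits.
#' @export
read_hit_table <- function(path, significance = 0.1) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("hit_id", "seq_id", "start", "end", "total_E", "high_E",
            "low_E", "engine")
  if (!all(need %in% names(df)))
    stop("hit TSV needs columns: ", paste(need, collapse = ", "))
  if (!"label" %in% names(df))
    df$label <- label_hit(df$total_E, df$high_E, df$low_E, significance)
  df
}
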