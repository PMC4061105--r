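# Partition a domain model's positions into fold-critical (FOLD) vs
# remnant (REMNANT) segments, using DSSP labels, a CLUSTALX-style
# alignment quality score, or SEG-derived low-complexity probabilities.

#' DSSP labels treated as structural
#'
#' H = alpha helix, B = isolated beta-bridge, E = strand, G = 3/10 helix,
#' I = pi helix, T = turn, S = bend. The unstructured set is the blank
#' loop code and the alignment gap `-`.
#' @export
DSSP_STRUCTURAL <- c("H", "B", "E", "G", "I", "T", "S")

#' @rdname DSSP_STRUCTURAL
#' @export
DSSP_UNSTRUCTURED <- c(" ", "", "-")

#' Construct a model segmentation
#'
#' @param classes character vector over positions 1..K with values
#'   `"FOLD"` or `"REMNANT"`.
#' @param scheme which segmentation scheme produced it.
#' @param cutoff the cutoff used (if any).
#' @return Object of class `segmentation`: list with `length`, `classes`,
#'   `intervals` (data frame `start`, `end`, `class` of maximal runs,
#'   1-based closed, tiling 1..K), `scheme`, `cutoff`.
#' @export
segmentation <- function(classes, scheme = "manual", cutoff = NA_real_) {
  if (!length(classes)) stop("empty segmentation")
  if (!all(classes %in% c("FOLD", "REMNANT")))
    stop("classes must be 'FOLD' or 'REMNANT'")
  r <- rle(classes)
  end <- cumsum(r$lengths)
  structure(list(length = length(classes), classes = classes,
                 intervals = data.frame(start = end - r$lengths + 1L,
                                        end = end, class = r$values),
                 scheme = scheme, cutoff = cutoff),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation (%s): %d positions, %d FOLD / %d REMNANT in %d interval(s)\n",
              x$scheme, x$length, sum(x$classes == "FOLD"),
              sum(x$classes == "REMNANT"), nrow(x$intervals)))
  invisible(x)
}

#' Read/write segmentations as TSV intervals
#'
#' Columns `model_start`, `model_end`, `class` (1-based closed intervals
#' that must tile 1..K).
#' @param path file path.
#' @return a [segmentation].
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("model_start", "model_end", "class") %in% names(df)))
    stop("segment TSV needs columns model_start, model_end, class")
  df <- df[order(df$model_start), ]
  K <- max(df$model_end)
  cl <- rep(NA_character_, K)
  for (i in seq_len(nrow(df)))
    cl[df$model_start[i]:df$model_end[i]] <- toupper(df$class[i])
  if (any(is.na(cl))) stop("segment intervals do not tile 1..K")
  segmentation(cl, scheme = "file")
}

#' @rdname read_segments
#' @param seg a [segmentation].
#' @export
write_segments <- function(seg, path) {
  utils::write.table(
    data.frame(model_start = seg$intervals$start,
               model_end = seg$intervals$end, class = seg$intervals$class),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# BLOSUM62 restricted to the 20 standard residues, rows/cols in
# HMM_ALPHABET order
blosum62_20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[HMM_ALPHABET, HMM_ALPHABET]
    }
    cache
  }
})

#' Per-column alignment quality profile
#'
#' CLUSTALX-style conservation measure. For column j the consensus vector
#' is \eqn{X_j = (1/M) F_j^T C} where \eqn{F_j} counts residues in the
#' column and C is the substitution matrix (BLOSUM62 by default). Each
#' non-gap residue's distance to the consensus is the Euclidean norm
#' \eqn{D_{ij} = \sqrt{\sum_r (X_{rj} - c_{r,a_{ij}})^2}} (set
#' `distance = "signed"` for the plain signed sum of differences). The
#' raw quality \eqn{Q_j = \sum_i D_{ij} / M} is inverted and min-max
#' normalised to \eqn{\hat Q_j \in [0,1]} over the alignment's columns,
#' then down-weighted by the non-gap fraction:
#' \eqn{\tilde Q_j = (k_j/M) \hat Q_j}.
#'
#' When all columns share the same raw quality (a perfectly homogeneous
#' alignment) the min-max normalisation is degenerate and every
#' \eqn{\hat Q_j} is set to 1.
#'
#' @param aln an [msa].
#' @param substitution_matrix symmetric 20 x 20 score matrix with residue
#'   dimnames; defaults to BLOSUM62.
#' @param distance `"euclidean"` (default) or `"signed"`.
#' @return Object of class `quality_profile`: list with `X` (20 x N
#'   consensus vectors), `D` (M x N distances, NA at gaps), `Q`, `Q_hat`,
#'   `Q_tilde`, `k` (valid residues per column), `M`, `n_col`.
#' @export
quality_profile <- function(aln, substitution_matrix = NULL,
                            distance = c("euclidean", "signed")) {
  distance <- match.arg(distance)
  stopifnot(inherits(aln, "msa"))
  C <- substitution_matrix %||% blosum62_20()
  C <- C[HMM_ALPHABET, HMM_ALPHABET]
  M <- aln$n_seq; N <- aln$n_col
  bad <- setdiff(unique(as.vector(aln$mat)), c(HMM_ALPHABET, GAP))
  if (length(bad))
    stop("residue(s) outside the 20-letter alphabet: ",
         paste(bad, collapse = ", "))

  X <- matrix(0, 20L, N, dimnames = list(HMM_ALPHABET, NULL))
  D <- matrix(NA_real_, M, N)
  k <- integer(N)
  for (j in seq_len(N)) {
    col <- aln$mat[, j]
    valid <- col != GAP
    k[j] <- sum(valid)
    if (k[j] == 0L) next
    f <- table(factor(col[valid], levels = HMM_ALPHABET))
    X[, j] <- as.vector(crossprod(C, as.numeric(f))) / M
    for (i in which(valid)) {
      d <- X[, j] - C[, col[i]]
      D[i, j] <- if (distance == "euclidean") sqrt(sum(d^2)) else sum(d)
    }
  }
  Q <- colSums(D, na.rm = TRUE) / M
  rng <- range(Q)
  Q_hat <- if (rng[2] > rng[1]) 1 - (Q - rng[1]) / (rng[2] - rng[1])
           else rep(1, N)
  structure(list(X = X, D = D, Q = Q, Q_hat = Q_hat,
                 Q_tilde = (k / M) * Q_hat, k = k, M = M, n_col = N),
            class = "quality_profile")
}

#' Binomial tail for the minimum-sequence rule
#'
#' Exact one-sided binomial tail \eqn{P(X \ge k)} at p = 0.5 for a column
#' of M sequences with k positive indicators. With fewer than 5 sequences
#' the smallest attainable p-value exceeds 0.05, so such columns carry no
#' statistical power at that level.
#'
#' @param M number of sequences (non-gap residues) in the column.
#' @param k number of positives, `0 <= k <= M`.
#' @return the tail probability.
#' @export
min_sequence_pvalue <- function(M, k) {
  if (any(k > M) || any(k < 0) || any(M < 1))
    stop("require 0 <= k <= M and M >= 1")
  stats::pbinom(k - 1, M, 0.5, lower.tail = FALSE)
}

#' Segment a model by quality score
#'
#' Positions with \eqn{\tilde Q \ge} `cutoff` are labelled FOLD
#' (high-quality), the rest REMNANT; maximal runs form the intervals.
#'
#' @param profile a [quality_profile], or a numeric vector of
#'   \eqn{\tilde Q} values mapping 1:1 to model positions.
#' @param cutoff quality-score threshold in `[0, 1]`. 0.06 suits
#'   SMART-like seed alignments, 0.14 Pfam-like ones (both at a 5\% false
#'   positive rate against sparse columns; see [calibrate_cutoff()]).
#' @param model_length optional check that the profile matches the model.
#' @return a [segmentation] with `scheme = "quality"`.
#' @export
segment_by_quality <- function(profile, cutoff = 0.06,
                               model_length = NULL) {
  qt <- if (inherits(profile, "quality_profile")) profile$Q_tilde
        else as.numeric(profile)
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  if (!is.null(model_length) && length(qt) != model_length)
    stop("profile length differs from model length")
  segmentation(ifelse(qt >= cutoff, "FOLD", "REMNANT"),
               scheme = "quality", cutoff = cutoff)
}

#' Segment a model by DSSP structural labels
#'
#' Positions carrying a label in `DSSP_STRUCTURAL` become FOLD; the loop
#' code and the gap marker become REMNANT.
#'
#' @param ann a `residue_annotation` (see [project_dssp_to_model()]) or a
#'   plain character vector of labels over positions 1..K.
#' @return a [segmentation] with `scheme = "dssp"`.
#' @export
segment_by_dssp <- function(ann) {
  lab <- as.character(ann)
  unknown <- setdiff(unique(lab), c(DSSP_STRUCTURAL, DSSP_UNSTRUCTURED))
  if (length(unknown))
    stop("unknown DSSP label(s): ",
         paste(shQuote(unknown), collapse = ", "))
  segmentation(ifelse(lab %in% DSSP_STRUCTURAL, "FOLD", "REMNANT"),
               scheme = "dssp")
}

#' SEG-derived column probability
#'
#' For one alignment column, `flags` holds an indicator per (non-gap)
#' sequence: 1 = high-complexity (positive prediction), 0 = flagged
#' low-complexity by SEG. The binomial tail [min_sequence_pvalue()] is
#' tested at `alpha`; on rejection the expected positive count is
#' \eqn{k_{exp} = P(X \ge k) k} (or \eqn{(1 - P(X \ge k)) k} with
#' `complement = TRUE`; see the package vignette for why the literal
#' product is kept as the default), otherwise \eqn{k_{exp} = 0}. The
#' column probability is \eqn{p_{exp} = 0.01} when \eqn{k_{exp} = 0} and
#' \eqn{k_{exp}/M} otherwise; the column counts as high-complexity when
#' \eqn{p_{exp} \ge} `cutoff`.
#'
#' @param flags 0/1 vector (NAs, e.g. gaps, are dropped).
#' @param alpha significance level for the binomial test (default 0.05).
#' @param cutoff segment cutoff on `p_exp` (default 0.8).
#' @param complement use \eqn{(1 - P(X \ge k)) k} for \eqn{k_{exp}}.
#' @return list with `M`, `k`, `p_value`, `k_exp`, `p_exp`,
#'   `high_complexity`.
#' @export
seg_column_probability <- function(flags, alpha = 0.05, cutoff = 0.8,
                                   complement = FALSE) {
  flags <- flags[!is.na(flags)]
  if (!length(flags)) stop("empty column")
  if (!all(flags %in% c(0, 1))) stop("flags must be 0/1")
  M <- length(flags); k <- sum(flags)
  p <- min_sequence_pvalue(M, k)
  k_exp <- if (p < alpha) (if (complement) (1 - p) * k else p * k) else 0
  p_exp <- if (k_exp == 0) 0.01 else k_exp / M
  list(M = M, k = k, p_value = p, k_exp = k_exp, p_exp = p_exp,
       high_complexity = p_exp >= cutoff)
}

#' Segment a model from a SEG low-complexity mask
#'
#' @param mask M x N matrix of 0/1 indicators over alignment columns
#'   (1 = high-complexity residue, 0 = SEG-flagged low-complexity, NA =
#'   gap), e.g. SEG output projected from the ungapped sequences back
#'   onto alignment columns.
#' @inheritParams seg_column_probability
#' @return a [segmentation] with `scheme = "seg"` (high-complexity
#'   columns are FOLD).
#' @export
segment_by_seg <- function(mask, alpha = 0.05, cutoff = 0.8,
                           complement = FALSE) {
  cl <- apply(mask, 2L, function(col) {
    if (all(is.na(col))) return("REMNANT")
    p <- seg_column_probability(col, alpha, cutoff, complement)
    if (p$high_complexity) "FOLD" else "REMNANT"
  })
  segmentation(cl, scheme = "seg", cutoff = cutoff)
}

#' True/false positive rates from confusion counts
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`.
#' @param tp,fn,fp,tn non-negative counts (vectorised).
#' @return data frame with columns `TPR` and `FPR`.
#' @export
confusion_rates <- function(tp, fn, fp, tn) {
  data.frame(TPR = tp / (tp + fn), FPR = fp / (fp + tn))
}

#' Calibrate the quality-score cutoff against sparse columns
#'
#' Columns with at least 5 valid residues form the positive class, those
#' with fewer the negative (null) class: below 5 sequences the
#' minimum-sequence binomial test has no power at alpha = 0.05 and such
#' sparse columns are typical of weak alignment segments. A column is
#' *called* positive at a given cutoff when its \eqn{\tilde Q} reaches
#' it; tabulating the confusion counts over a cutoff grid yields the
#' false/true positive rates used to pick an operating point.
#'
#' @param qt_scores_ge5 \eqn{\tilde Q} values from columns with >= 5
#'   residues.
#' @param qt_scores_lt5 \eqn{\tilde Q} values from columns with < 5
#'   residues.
#' @param grid cutoff grid (default 0.01 to 0.99 by 0.01).
#' @return data frame with columns `cutoff`, `TP`, `FN`, `FP`, `TN`,
#'   `FPR`, `TPR`.
#' @export
calibrate_cutoff <- function(qt_scores_ge5, qt_scores_lt5,
                             grid = seq(0.01, 0.99, by = 0.01)) {
  if (!length(qt_scores_ge5) || !length(qt_scores_lt5))
    stop("both score classes must be non-empty")
  tab <- t(vapply(grid, function(cut) {
    c(TP = sum(qt_scores_ge5 >= cut), FN = sum(qt_scores_ge5 < cut),
      FP = sum(qt_scores_lt5 >= cut), TN = sum(qt_scores_lt5 < cut))
  }, numeric(4)))
  rates <- confusion_rates(tab[, "TP"], tab[, "FN"], tab[, "FP"],
                           tab[, "TN"])
  data.frame(cutoff = grid, tab, FPR = rates$FPR, TPR = rates$TPR)
}
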