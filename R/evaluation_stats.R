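# Statistical support: no-intercept reproduction regression, the
# reconstruction-error model, and the one-tailed Fisher/hypergeometric
# enrichment test of structural residues in high-quality segments.

#' No-intercept regression of reconstructed on original scores
#'
#' Tests the linear relationship W = v between original scores v and
#' reconstructed scores w for one domain. Because seed-sequence scores of
#' a domain cluster tightly, a point at the origin is appended before
#' fitting to anchor the no-intercept line; for well-spread scores it has
#' little effect. The slope is \eqn{\hat\beta = \sum w v / \sum v^2} and
#' the goodness of fit is the squared product-moment correlation.
#'
#' @param original scores v.
#' @param reconstructed scores w (same length).
#' @return list with `slope`, `r_squared` (clamped to `[0, 1]`) and
#'   `n_points` (including the origin point).
#' @export
regress_no_intercept <- function(original, reconstructed) {
  if (!length(original) || length(original) != length(reconstructed))
    stop("need equal-length non-empty score vectors")
  v <- c(original, 0)
  w <- c(reconstructed, 0)
  if (all(v == 0)) stop("all original scores are zero")
  P <- length(v)
  slope <- sum(w * v) / sum(v^2)
  sxy <- sum(v * w) - sum(v) * sum(w) / P
  sxx <- sum(v^2) - sum(v)^2 / P
  syy <- sum(w^2) - sum(w)^2 / P
  r2 <- if (sxx > 0 && syy > 0) sxy^2 / (sxx * syy) else NA_real_
  list(slope = slope, r_squared = min(max(r2, 0), 1), n_points = P)
}

#' Reconstruction error model
#'
#' Models the reconstructed score as W = v + eps and summarises eps over
#' the P score pairs of one domain: mean error, population variance
#' (divisor P), and the relative error \eqn{\epsilon_r = \mu_\epsilon /
#' \mu_v} against the representative (mean original) domain score.
#'
#' @inheritParams regress_no_intercept
#' @return list with `mean_error`, `error_variance`, `relative_error`,
#'   `representative_score`.
#' @export
error_estimate <- function(original, reconstructed) {
  if (!length(original) || length(original) != length(reconstructed))
    stop("need equal-length non-empty score vectors")
  eps <- reconstructed - original
  mu_eps <- mean(eps)
  mu_v <- mean(original)
  if (mu_v == 0) stop("mean original score is zero; relative error undefined")
  list(mean_error = mu_eps,
       error_variance = mean((eps - mu_eps)^2),
       relative_error = mu_eps / mu_v,
       representative_score = mu_v)
}

#' One-tailed hypergeometric enrichment p-value
#'
#' For a 2x2 table with cells f11 (high-quality & structural), f12, f21,
#' f22, computes the strictly-greater tail \eqn{P(X > f_{11}) = 1 - P(X
#' \le f_{11})} of the hypergeometric distribution with the table's
#' margins. Note the strict inequality: the observed cell itself is
#' excluded. `inclusive = TRUE` gives the conventional one-tailed Fisher
#' tail \eqn{P(X \ge f_{11})}.
#'
#' @param f11,f12,f21,f22 non-negative cell counts.
#' @param inclusive include the observed table in the tail.
#' @return the p-value.
#' @export
fisher_enrichment <- function(f11, f12, f21, f22, inclusive = FALSE) {
  if (any(c(f11, f12, f21, f22) < 0)) stop("cell counts must be >= 0")
  C1 <- f11 + f21          # structural residues
  C2 <- f12 + f22          # non-structural
  R1 <- f11 + f12          # high-quality residues
  q <- if (inclusive) f11 - 1 else f11
  stats::phyper(q, C1, C2, R1, lower.tail = FALSE)
}

#' Enrichment of structural residues in fold-critical segments
#'
#' Cross-tabulates the segmentation class (FOLD / REMNANT) against the
#' DSSP label class (structural / unstructured) and applies
#' [fisher_enrichment()]. Setting `direction = "unstructured"` runs the
#' control test for enrichment of non-structural residues in FOLD
#' segments.
#'
#' @param seg a [segmentation].
#' @param ann a `residue_annotation` or character label vector of the
#'   same length.
#' @param alpha significance level (default 0.05).
#' @param direction `"structural"` (default) or `"unstructured"`.
#' @param inclusive passed to [fisher_enrichment()].
#' @return list with `table` (named cell counts f11, f12, f21, f22),
#'   `p_value` and `enriched` (p < alpha).
#' @export
enrichment_test <- function(seg, ann, alpha = 0.05,
                            direction = c("structural", "unstructured"),
                            inclusive = FALSE) {
  direction <- match.arg(direction)
  lab <- as.character(ann)
  if (length(lab) != seg$length)
    stop("segmentation and annotation lengths differ")
  structural <- lab %in% DSSP_STRUCTURAL
  if (direction == "unstructured") structural <- !structural
  fold <- seg$classes == "FOLD"
  tab <- c(f11 = sum(fold & structural), f12 = sum(fold & !structural),
           f21 = sum(!fold & structural), f22 = sum(!fold & !structural))
  p <- fisher_enrichment(tab["f11"], tab["f12"], tab["f21"], tab["f22"],
                         inclusive = inclusive)
  list(table = tab, p_value = unname(p), enriched = unname(p < alpha))
}
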