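# Score reconstruction from model parameters, segment-wise dissection,
# and Gumbel extreme-value E-values.
#
# The total log-odds score of an alignment is the sum of per-step
# emission scores, per-step transition scores (including the begin->match
# entry and match->end exit) and the position-invariant fixed score f.
# Every emission/transition term is anchored to a model coordinate so the
# partition into segment classes is total:
#   * an emission at model position k belongs to k's class;
#   * a transition INTO position k (M_{k-1}->M_k, D->M_k, B->M_k, ...)
#     belongs to k's class;
#   * the exit M_K->E belongs to K's class;
#   * insert emissions and I->I self-transitions belong to the class of
#     the last MATCH/DELETE model position visited.

#' Default comparison database size
#'
#' Number of sequences used to scale E-values unless overridden
#' (UniProt/SwissProt, April 2013).
#' @export
DEFAULT_DB_SIZE <- 540261

# per-term breakdown of the reconstructed score: data frame with columns
# term, model_pos, score. Entry/exit transitions that the model marks
# impossible (-Inf; e.g. local entries dropped by hmmconvert) are treated
# as unavailable and omitted, with a count kept in attr "dropped_entries".
# -Inf anywhere else propagates.
score_terms <- function(path, model) {
  K <- model$length
  if (any(path$model_pos > K, na.rm = TRUE))
    stop("path visits model position beyond model length K = ", K)
  aa_idx <- stats::setNames(seq_along(HMM_ALPHABET), HMM_ALPHABET)
  term <- character(0); mp <- integer(0); sc <- numeric(0)
  dropped <- 0L
  add <- function(t, k, s) {
    term <<- c(term, t); mp <<- c(mp, k); sc <<- c(sc, s)
  }
  for (f in unique(path$fragment)) {
    fr <- path[path$fragment == f, , drop = FALSE]
    n <- nrow(fr)
    # entry into the fragment's first state
    if (fr$state[1] %in% c("M", "D")) {
      k1 <- fr$model_pos[1]
      bm <- model$transition[k1, "BM"]
      if (is.finite(bm)) add("B->M", k1, bm) else dropped <- dropped + 1L
    }
    for (i in seq_len(n)) {
      st <- fr$state[i]; k <- fr$model_pos[i]
      if (i > 1L) {
        prev <- fr$state[i - 1L]; kp <- fr$model_pos[i - 1L]
        tt <- paste0(prev, st)       # MM, MI, MD, IM, II, DM, DD, (ID/DI)
        if (!tt %in% HMM_TRANSITIONS)
          stop("transition ", prev, "->", st,
               " has no score in the HMMER2 parameterisation")
        # pair transitions are stored on the source state's row
        add(paste0(prev, "->", st), k, model$transition[kp, tt])
      }
      if (st == "M") {
        add("emit M", k, model$match_emission[k, aa_idx[[residue_of(fr, i)]]])
      } else if (st == "I") {
        add("emit I", k, model$insert_emission[k, aa_idx[[residue_of(fr, i)]]])
      }
    }
    # exit from the fragment's last match state
    last_m <- which(fr$state == "M")
    if (length(last_m)) {
      kx <- fr$model_pos[max(last_m)]
      mex <- model$transition[kx, "ME"]
      if (is.finite(mex)) add("M->E", kx, mex) else dropped <- dropped + 1L
    }
  }
  structure(data.frame(term = term, model_pos = mp, score = sc),
            dropped_entries = dropped)
}

# residue emitted at step i; paths may carry an explicit `residue`
# column, otherwise emissions are looked up via attr(path, "sequence")
residue_of <- function(fr, i) {
  if ("residue" %in% names(fr)) return(fr$residue[i])
  stop("path carries no residues: add a 'residue' column or use ",
       "attach_sequence()")
}

#' Attach the hit sequence's residues to a path
#'
#' Fills a `residue` column from the hit sequence so emission scores can
#' be looked up.
#' @param path an [alignment_path].
#' @param sequence the hit protein sequence (plain string, 1-based
#'   residue numbering matching `seq_pos`).
#' @return the path with a `residue` column.
#' @export
attach_sequence <- function(path, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (any(path$seq_pos > length(chars), na.rm = TRUE))
    stop("path references residues beyond the sequence length")
  res <- rep(NA_character_, nrow(path))
  emit <- path$state %in% c("M", "I")
  res[emit] <- chars[path$seq_pos[emit]]
  path$residue <- res
  path
}

#' Reconstruct the total log-odds score of an alignment
#'
#' Sums emission and transition scores along the path, plus the fixed
#' score f from the model's XT line. Any `-Inf` emission or internal
#' transition makes the total `-Inf`. Begin/end transitions that the
#' model marks impossible (the local entries `hmmconvert -2` drops) are
#' omitted rather than propagated, which is the source of the small,
#' documented approximation for fragmented local alignments.
#'
#' @param path an [alignment_path] with residues attached.
#' @param model an `hmm_model`.
#' @param fixed include the fixed score f (default TRUE).
#' @return total score v in bits.
#' @export
reconstruct_score <- function(path, model, fixed = TRUE) {
  v <- sum(score_terms(path, model)$score)
  if (fixed) v <- v + fixed_score(model)
  v
}

#' Gumbel extreme-value E-value
#'
#' \eqn{E = N (1 - e^{-e^{-\lambda (v - \mu)}})}, the expected number of
#' chance hits scoring at least v under the maximum Gumbel distribution.
#' Computed via `expm1` so that large scores fall back to the asymptotic
#' \eqn{N e^{-\lambda (v - \mu)}} instead of underflowing to zero.
#'
#' @param v score in bits.
#' @param model an `hmm_model` providing `(mu, lambda)`; alternatively
#'   pass `mu` and `lambda` directly.
#' @param db_size database size N (default `DEFAULT_DB_SIZE`).
#' @param mu,lambda explicit Gumbel parameters (required when the model
#'   is uncalibrated).
#' @return E-value in `[0, N]` (vectorised over `v`).
#' @export
evalue <- function(v, model = NULL, db_size = DEFAULT_DB_SIZE,
                   mu = NULL, lambda = NULL) {
  if (is.null(mu)) mu <- model$evd_mu
  if (is.null(lambda)) lambda <- model$evd_lambda
  if (is.null(mu) || is.null(lambda) || is.na(mu) || is.na(lambda))
    stop("model is uncalibrated: supply mu and lambda explicitly")
  if (lambda <= 0) stop("lambda must be positive")
  if (db_size < 1) stop("db_size must be at least 1")
  logx <- -lambda * (v - mu)
  ifelse(logx < -700,
         db_size * exp(logx),                   # deep-tail asymptotics
         db_size * -expm1(-exp(logx)))
}

#' Ratio of fold-critical to remnant E-value
#'
#' \eqn{E_1 / E_2}. A ratio much below 1 says the fold-critical component
#' is the significant one (homology-supporting); much above 1 flags a
#' spurious similarity carried by remnant segments.
#'
#' @param fold_evalue,remnant_evalue the two segment-class E-values.
#' @return the ratio.
#' @export
evalue_ratio <- function(fold_evalue, remnant_evalue) {
  if (any(remnant_evalue <= 0)) stop("remnant E-value must be positive")
  if (any(fold_evalue < 0)) stop("E-values cannot be negative")
  fold_evalue / remnant_evalue
}

#' @rdname evalue_ratio
#' @param ratio value from [evalue_ratio()].
#' @param band half-decade band around 1 regarded as on-par (default 2,
#'   i.e. ratios in `[1/2, 2]`).
#' @return `"homology-supporting"`, `"on-par"` or `"spurious"`.
#' @export
ratio_verdict <- function(ratio, band = 2) {
  ifelse(ratio < 1 / band, "homology-supporting",
         ifelse(ratio > band, "spurious", "on-par"))
}

#' Dissect an alignment score into segment-class contributions
#'
#' Reconstructs every emission/transition term of the alignment score,
#' assigns each term to the FOLD or REMNANT class of its governing model
#' position, and evaluates the total (including the fixed score f) and
#' the two class sums independently as E-values under the model's single
#' Gumbel calibration. For multi-fragment hits the fragment contributions
#' are summed per class before the E-values are taken.
#'
#' @param path an [alignment_path] with residues attached (see
#'   [attach_sequence()]).
#' @param model an `hmm_model`.
#' @param seg a [segmentation] covering positions 1..K.
#' @param db_size database size N for E-values.
#' @param mu,lambda optional Gumbel overrides for uncalibrated models.
#' @return Object of class `dissected_score`: list with `hit_id`,
#'   `total_score`, `fold_score`, `remnant_score`, `fixed`,
#'   `total_evalue`, `fold_evalue`, `remnant_evalue`, `ratio`, `verdict`,
#'   `db_size`, `fragment_scores` (per-fragment raw sums, approximate for
#'   fragmented local alignments) and `terms` (the full per-term table).
#' @export
dissect <- function(path, model, seg, db_size = DEFAULT_DB_SIZE,
                    mu = NULL, lambda = NULL) {
  if (seg$length != model$length)
    stop("segmentation covers ", seg$length,
         " positions but the model has ", model$length)
  terms <- score_terms(path, model)
  terms$class <- seg$classes[terms$model_pos]
  f <- fixed_score(model)
  fold <- sum(terms$score[terms$class == "FOLD"])
  remn <- sum(terms$score[terms$class == "REMNANT"])
  total <- fold + remn + f
  frag_rows <- split(seq_len(nrow(path)), path$fragment)
  frag_scores <- vapply(unique(path$fragment), function(fr)
    sum(score_terms(path[path$fragment == fr, , drop = FALSE],
                    model)$score), numeric(1))
  E <- function(s) evalue(s, model, db_size, mu = mu, lambda = lambda)
  e_tot <- E(total); e1 <- E(fold); e2 <- E(remn)
  structure(list(hit_id = attr(path, "hit_id"),
                 engine = attr(path, "engine"),
                 total_score = total, fold_score = fold,
                 remnant_score = remn, fixed = f,
                 total_evalue = e_tot, fold_evalue = e1,
                 remnant_evalue = e2,
                 ratio = if (e2 > 0) e1 / e2 else NA_real_,
                 verdict = if (e2 > 0) ratio_verdict(e1 / e2)
                           else NA_character_,
                 db_size = db_size,
                 fragment_scores = frag_scores,
                 dropped_entries = attr(terms, "dropped_entries"),
                 terms = terms),
            class = "dissected_score")
}

#' @export
print.dissected_score <- function(x, ...) {
  cat(sprintf("Dissected score for hit '%s' (%s)\n", x$hit_id, x$engine))
  cat(sprintf("  total   %9.2f bits  E = %.3g\n",
              x$total_score, x$total_evalue))
  cat(sprintf("  fold    %9.2f bits  E1 = %.3g\n",
              x$fold_score, x$fold_evalue))
  cat(sprintf("  remnant %9.2f bits  E2 = %.3g\n",
              x$remnant_score, x$remnant_evalue))
  cat(sprintf("  fixed f %9.2f bits\n", x$fixed))
  cat(sprintf("  E1/E2 = %.3g (%s)\n", x$ratio, x$verdict))
  invisible(x)
}

#' Tabulate dissected scores for a set of hits
#'
#' @param paths list of [alignment_path] objects (residues attached).
#' @param model an `hmm_model`.
#' @param seg a [segmentation].
#' @inheritParams dissect
#' @return data frame with one row per hit: `hit_id`, `v`, `fold_score`,
#'   `remnant_score`, `f`, `E`, `E1`, `E2`, `ratio`, `verdict`.
#' @export
dissect_hits <- function(paths, model, seg, db_size = DEFAULT_DB_SIZE,
                         mu = NULL, lambda = NULL) {
  rows <- lapply(paths, function(p) {
    d <- dissect(p, model, seg, db_size, mu, lambda)
    data.frame(hit_id = d$hit_id, v = d$total_score,
               fold_score = d$fold_score, remnant_score = d$remnant_score,
               f = d$fixed, E = d$total_evalue, E1 = d$fold_evalue,
               E2 = d$remnant_evalue, ratio = d$ratio,
               verdict = d$verdict)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
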