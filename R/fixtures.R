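# Synthetic models, alignments, annotations and hit sets with known
# ground truth. Everything is generated from an explicit seed so the
# same call is byte-identical across sessions. The naive per-term score
# oracle lives here, NOT in the production scoring path, so
# oracle-vs-implementation tests are genuinely independent.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

r_int_scores <- function(n, lo, hi) {
  sample(seq.int(lo, hi), n, replace = TRUE) / 1000
}

#' Generate a random profile HMM
#'
#' Scores are drawn as 1/1000-bit integers so written files round-trip
#' exactly. By default the model is glocal-style: begin->match entry
#' exists only into state 1 and match->end exit only out of state K,
#' with the other entries/exits the `-Inf` sentinel (as in models
#' converted from local parameterisations). `local_entry = TRUE` draws
#' finite entry/exit scores for every state instead.
#'
#' @param K number of match states.
#' @param seed RNG seed.
#' @param calibrated attach a Gumbel (mu, lambda) calibration.
#' @param local_entry finite B->M/M->E at every state.
#' @return an `hmm_model`.
#' @export
make_model <- function(K = 8L, seed = 1L, calibrated = TRUE,
                       local_entry = FALSE) {
  with_seed(seed, {
    me <- matrix(r_int_scores(20L * K, -5000, 5000), K, 20L)
    ie <- matrix(r_int_scores(20L * K, -2000, 1000), K, 20L)
    ie[K, ] <- -Inf                       # no insert state after M_K
    tr <- matrix(-Inf, K, 9L, dimnames = list(NULL, HMM_TRANSITIONS))
    tr[, "MM"] <- r_int_scores(K, -200, 0)
    tr[, "MI"] <- r_int_scores(K, -8000, -500)
    tr[, "MD"] <- r_int_scores(K, -9000, -1000)
    tr[, "IM"] <- r_int_scores(K, -2000, -200)
    tr[, "II"] <- r_int_scores(K, -2000, -200)
    tr[, "DM"] <- r_int_scores(K, -1500, -200)
    tr[, "DD"] <- r_int_scores(K, -2500, -500)
    tr[K, c("MM", "MI", "MD", "IM", "II", "DM", "DD")] <- -Inf
    if (local_entry) {
      tr[, "BM"] <- r_int_scores(K, -3000, 0)
      tr[, "ME"] <- r_int_scores(K, -3000, 0)
    } else {
      tr[1L, "BM"] <- r_int_scores(1L, -100, 0)
      tr[K, "ME"] <- 0
    }
    xt <- stats::setNames(r_int_scores(8L, -9000, 0), HMM_XT_NAMES)
    hmm_model(name = sprintf("fix%d_K%d", seed, K),
              match_emission = me, insert_emission = ie, transition = tr,
              xt = xt, nult = c(-0.004, -8.455),
              nule = r_int_scores(20L, -2000, 1000),
              evd_mu = if (calibrated) round(stats::runif(1, -60, -5), 3)
                       else NA_real_,
              evd_lambda = if (calibrated)
                             round(stats::runif(1, 0.15, 0.7), 3)
                           else NA_real_,
              b_line = c(r_int_scores(1L, -100, 0), -Inf,
                         r_int_scores(1L, -9000, -1000)))
  })
}

#' Naive per-term score oracle
#'
#' Literal, step-by-step summation of the alignment log-odds score:
#' emission of every MATCH/INSERT step, the transition between each
#' consecutive pair of states, the begin->match entry, the match->end
#' exit, and the fixed score. Written as a plain loop, independent of
#' the production reconstruction, to serve as the reference in
#' equivalence tests.
#'
#' @param path an [alignment_path] with a `residue` column.
#' @param model an `hmm_model`.
#' @param fixed include the fixed score.
#' @return score in bits.
#' @export
naive_path_score <- function(path, model, fixed = TRUE) {
  total <- if (fixed) {
    model$xt[["NB"]] + model$xt[["EC"]] + model$xt[["CT"]]
  } else 0
  for (f in unique(path$fragment)) {
    fr <- path[path$fragment == f, , drop = FALSE]
    if (fr$state[1] == "M" || fr$state[1] == "D") {
      b <- model$transition[fr$model_pos[1], "BM"]
      if (!is.infinite(b)) total <- total + b
    }
    last_match <- NA_integer_
    for (i in seq_len(nrow(fr))) {
      s <- fr$state[i]
      k <- fr$model_pos[i]
      if (i > 1) {
        ps <- fr$state[i - 1]
        pk <- fr$model_pos[i - 1]
        total <- total + model$transition[pk, paste0(ps, s)]
      }
      if (s == "M") {
        total <- total + model$match_emission[k, fr$residue[i]]
        last_match <- k
      } else if (s == "I") {
        total <- total + model$insert_emission[k, fr$residue[i]]
      }
    }
    if (!is.na(last_match)) {
      e <- model$transition[last_match, "ME"]
      if (!is.infinite(e)) total <- total + e
    }
  }
  unname(total)
}

#' Generate a random alignment path with its hand-summed score
#'
#' Draws a glocal-style path through the model (every position visited
#' as MATCH or DELETE, with optional insert runs after match states) and
#' returns it together with the score from the naive oracle.
#'
#' @param model an `hmm_model`.
#' @param seed RNG seed.
#' @param p_delete per-position probability of a DELETE.
#' @param p_insert probability of opening an insert run after a match.
#' @param hit_id identifier given to the path.
#' @return list with `path` (residues attached) and `hand_score` (bits).
#' @export
make_alignment_with_truth <- function(model, seed = 1L, p_delete = 0.1,
                                      p_insert = 0.1,
                                      hit_id = paste0("hit", seed)) {
  K <- model$length
  with_seed(seed, {
    state <- character(0); mp <- integer(0); sp <- integer(0)
    res <- character(0)
    s <- 0L
    in_insert <- FALSE
    for (k in seq_len(K)) {
      # deletions never at position 1 (paths enter at M1) nor at K, and
      # never straight after an insert run (I->D has no HMMER2 score)
      del <- k > 1L && k < K && !in_insert && stats::runif(1) < p_delete
      in_insert <- FALSE
      if (del) {
        state <- c(state, "D"); mp <- c(mp, k); sp <- c(sp, NA_integer_)
        res <- c(res, NA_character_)
      } else {
        s <- s + 1L
        state <- c(state, "M"); mp <- c(mp, k); sp <- c(sp, s)
        res <- c(res, sample(HMM_ALPHABET, 1L))
        if (k < K && stats::runif(1) < p_insert) {
          for (r in seq_len(sample(1:3, 1L))) {
            s <- s + 1L
            state <- c(state, "I"); mp <- c(mp, k); sp <- c(sp, s)
            res <- c(res, sample(HMM_ALPHABET, 1L))
          }
          in_insert <- TRUE
        }
      }
    }
    path <- alignment_path(
      data.frame(fragment = 1L, state = state, model_pos = mp,
                 seq_pos = sp),
      hit_id = hit_id, engine = "fixture")
    path$residue <- res
    list(path = path, hand_score = naive_path_score(path, model))
  })
}

#' Generate a seed alignment with planted conservation blocks
#'
#' Conserved columns draw a column-specific consensus residue with
#' probability `conservation` (mismatches uniform over the remaining
#' residues); noisy columns draw uniformly over the 20 residues; gaps
#' are sprinkled independently. The planted truth labels conserved
#' columns FOLD and noisy ones REMNANT.
#'
#' @param M number of sequences.
#' @param conserved logical vector over columns (`TRUE` = conserved).
#' @param conservation consensus probability in conserved columns.
#' @param gap_prob per-cell gap probability.
#' @param seed RNG seed.
#' @return list with `aln` (an [msa]) and `truth` (`"FOLD"`/`"REMNANT"`
#'   per column).
#' @export
make_seed_alignment <- function(M = 8L, conserved, conservation = 0.95,
                                gap_prob = 0, seed = 1L) {
  N <- length(conserved)
  with_seed(seed, {
    mat <- matrix("", M, N)
    for (j in seq_len(N)) {
      if (conserved[j]) {
        cons <- sample(HMM_ALPHABET, 1L)
        hitcons <- stats::runif(M) < conservation
        mat[, j] <- ifelse(hitcons, cons,
                           sample(setdiff(HMM_ALPHABET, cons), M,
                                  replace = TRUE))
      } else {
        mat[, j] <- sample(HMM_ALPHABET, M, replace = TRUE)
      }
    }
    if (gap_prob > 0)
      mat[matrix(stats::runif(M * N) < gap_prob, M, N)] <- "-"
    list(aln = msa(apply(mat, 1L, paste, collapse = "")),
         truth = ifelse(conserved, "FOLD", "REMNANT"))
  })
}

#' Generate a DSSP-like annotation with planted structural blocks
#'
#' @param K model length.
#' @param frac_structural fraction of positions given a structural label.
#' @param seed RNG seed.
#' @return character vector over the DSSP alphabet plus the loop code.
#' @export
make_dssp_annotation <- function(K, frac_structural = 0.6, seed = 1L) {
  with_seed(seed, {
    lab <- rep(" ", K)
    n_s <- round(frac_structural * K)
    if (n_s > 0) {
      start <- sample(seq_len(K - n_s + 1L), 1L)
      lab[start:(start + n_s - 1L)] <-
        sample(DSSP_STRUCTURAL, n_s, replace = TRUE)
    }
    lab
  })
}

#' Generate paired synthetic hit tables for two engines
#'
#' Emulates a two-engine comparison on a common search: a fraction of
#' hits are planted true homologies (significant total and fold-critical
#' E-values), the rest false (significant remnant only, or nothing).
#' Engine B re-draws its E-values around engine A's with log-normal
#' jitter, and a small fraction of B's hits is shifted off-segment to
#' create orphans.
#'
#' @param n_hits number of target sequences.
#' @param frac_true fraction of planted true homologies.
#' @param jitter_sd log10-scale standard deviation between engines.
#' @param frac_orphan fraction of engine-B hits moved to a disjoint
#'   segment.
#' @param significance labelling threshold.
#' @param seed RNG seed.
#' @return list with `hits_a`, `hits_b` (labelled hit tables) and
#'   `truth` (logical: planted as true homology).
#' @export
make_hit_tables <- function(n_hits = 200L, frac_true = 0.8,
                            jitter_sd = 0.3, frac_orphan = 0.05,
                            significance = 0.1, seed = 1L) {
  with_seed(seed, {
    truth <- stats::runif(n_hits) < frac_true
    draw <- function(lo, hi) 10^stats::runif(n_hits, lo, hi)
    # planted true: fold-critical E small; total usually small too
    high_a <- ifelse(truth, draw(-8, -2), draw(0.5, 3))
    low_a  <- ifelse(truth, draw(0, 3), draw(-6, -2))
    tot_a  <- ifelse(truth,
                     ifelse(stats::runif(n_hits) < 0.85,
                            draw(-8, -2), draw(0, 1)),
                     draw(-3, 1))
    jit <- function(x) 10^(log10(x) + stats::rnorm(n_hits, 0, jitter_sd))
    start <- sample(1:400, n_hits, replace = TRUE)
    len <- sample(60:120, n_hits, replace = TRUE)
    mk <- function(tot, high, low, engine, start, end)
      data.frame(hit_id = paste0(engine, "_", seq_len(n_hits)),
                 seq_id = paste0("seq", seq_len(n_hits)),
                 start = start, end = end,
                 total_E = tot, high_E = high, low_E = low,
                 engine = engine,
                 label = label_hit(tot, high, low, significance))
    hits_a <- mk(tot_a, high_a, low_a, "engineA", start, start + len)
    off <- stats::runif(n_hits) < frac_orphan
    start_b <- ifelse(off, start + len + 50L,
                      start + sample(-10:10, n_hits, replace = TRUE))
    hits_b <- mk(jit(tot_a), jit(high_a), jit(low_a), "engineB",
                 start_b, start_b + len)
    list(hits_a = hits_a, hits_b = hits_b, truth = truth)
  })
}

#' Write a self-contained synthetic test bundle
#'
#' Generates a model file, a seed alignment (Stockholm), an explicit
#' alignment path (TSV), a DSSP-like label table, a SEG-like 0/1 mask
#' and labelled hit tables, all under one directory. Every file is
#' plain text and derived from `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param K model length.
#' @param M sequences in the seed alignment.
#' @return (invisibly) named vector of the paths written.
#' @export
write_fixture_bundle <- function(dir, seed = 1L, K = 30L, M = 8L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- make_model(K = K, seed = seed)
  fx <- make_alignment_with_truth(model, seed = seed)
  conserved <- rep(c(TRUE, FALSE), each = ceiling(K / 2))[seq_len(K)]
  seedaln <- make_seed_alignment(M = M, conserved = conserved,
                                 seed = seed)
  ann <- make_dssp_annotation(K, seed = seed)
  hits <- make_hit_tables(seed = seed)
  paths <- c(model = file.path(dir, "model.hmm2"),
             alignment = file.path(dir, "seed.sto"),
             path = file.path(dir, "path.tsv"),
             dssp = file.path(dir, "dssp_labels.tsv"),
             mask = file.path(dir, "seg_mask.tsv"),
             hits_a = file.path(dir, "hits_engineA.tsv"),
             hits_b = file.path(dir, "hits_engineB.tsv"))
  write_hmmer2_model(model, paths["model"])
  write_stockholm(seedaln$aln, paths["alignment"])
  write_path_tsv(fx$path, paths["path"])
  utils::write.table(data.frame(model_pos = seq_len(K), label = ann),
                     paths["dssp"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mask <- with_seed(seed, matrix(as.integer(stats::runif(M * K) < 0.7),
                                 M, K))
  utils::write.table(mask, paths["mask"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(hits$hits_a, paths["hits_a"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hits$hits_b, paths["hits_b"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
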