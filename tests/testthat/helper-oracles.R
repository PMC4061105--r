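# Independent brute-force oracles used to cross-check the production
# implementations. Each is a literal, loop-based transcription of the
# defining formula, kept free of any code from R/.

# per-column quality score, one equation at a time
oracle_quality <- function(mat, C) {
  M <- nrow(mat); N <- ncol(mat)
  aa <- rownames(C)
  Q <- numeric(N); k <- integer(N)
  for (j in seq_len(N)) {
    col <- mat[, j]
    # consensus vector: X_rj = (1/M) * sum_t F_tj * c_tr
    X <- numeric(length(aa)); names(X) <- aa
    for (r in aa) {
      acc <- 0
      for (t in aa) acc <- acc + sum(col == t) * C[t, r]
      X[r] <- acc / M
    }
    # distances for non-gap residues (euclidean)
    s <- 0
    for (i in seq_len(M)) {
      if (col[i] == "-") next
      k[j] <- k[j] + 1L
      d2 <- 0
      for (r in aa) d2 <- d2 + (X[r] - C[r, col[i]])^2
      s <- s + sqrt(d2)
    }
    Q[j] <- s / M
  }
  lo <- min(Q); hi <- max(Q)
  Q_hat <- if (hi > lo) 1 - (Q - lo) / (hi - lo) else rep(1, N)
  list(Q = Q, Q_hat = Q_hat, Q_tilde = (k / M) * Q_hat, k = k)
}

# strictly-greater hypergeometric tail by full enumeration of the support
oracle_fisher_tail <- function(f11, f12, f21, f22) {
  R1 <- f11 + f12; C1 <- f11 + f21; N <- f11 + f12 + f21 + f22
  lo <- max(0, R1 + C1 - N); hi <- min(R1, C1)
  total <- 0
  for (x in lo:hi) {
    if (x > f11)
      total <- total + choose(C1, x) * choose(N - C1, R1 - x)
  }
  total / choose(N, R1)
}

# binomial upper tail at p = 1/2 by direct summation
oracle_binom_tail <- function(M, k) {
  if (k <= 0) return(1)
  s <- 0
  for (x in k:M) s <- s + choose(M, x) * 0.5^x * 0.5^(M - x)
  s
}

# toy hand-set model used across dissection tests: K = 4, all scores
# chosen by hand so per-term sums are easy to verify on paper
hand_model <- function() {
  me <- matrix(0, 4, 20)
  me[cbind(1:4, 1:4)] <- c(1.0, 2.0, 0.5, 0.25)  # A,C,D,E diag scores
  ie <- matrix(-0.5, 4, 20)
  ie[4, ] <- -Inf
  tr <- matrix(-Inf, 4, 9,
               dimnames = list(NULL, hmmdissect::HMM_TRANSITIONS))
  tr[, "MM"] <- c(0.25, -0.125, -0.25, -Inf)
  tr[, "MI"] <- c(-1, -1, -1, -Inf)
  tr[, "MD"] <- c(-2, -2, -2, -Inf)
  tr[, "IM"] <- c(-0.5, -0.5, -0.5, -Inf)
  tr[, "II"] <- c(-1.5, -1.5, -1.5, -Inf)
  tr[, "DM"] <- c(-0.25, -0.25, -0.25, -Inf)
  tr[, "DD"] <- c(-0.75, -0.75, -0.75, -Inf)
  tr[1, "BM"] <- 0.5
  tr[4, "ME"] <- 0
  hmm_model(name = "hand", match_emission = me, insert_emission = ie,
            transition = tr,
            xt = stats::setNames(c(-0.25, 0, 0, 0, 0, 0, 0, 0),
                                 hmmdissect::HMM_XT_NAMES),
            nult = c(0, 0), nule = rep(0, 20),
            evd_mu = -10, evd_lambda = 0.5)
}

# full-length match-only path through a model, residues given per step
match_path <- function(residues, hit_id = "hand_hit") {
  K <- length(residues)
  p <- alignment_path(
    data.frame(fragment = 1L, state = rep("M", K),
               model_pos = seq_len(K), seq_pos = seq_len(K)),
    hit_id = hit_id, engine = "test")
  p$residue <- residues
  p
}

blosum20 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[hmmdissect::HMM_ALPHABET, hmmdissect::HMM_ALPHABET]
}
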