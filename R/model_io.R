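# HMMER2 ASCII profile-HMM save files: parsing, validation and writing.
#
# Scores in the save format are integer log2-odds in 1/1000-bit units;
# the character '*' marks an impossible transition/emission and maps to
# -Inf. All scores held in an `hmm_model` are in bits.

#' Amino-acid alphabet used by HMMER2 save files
#'
#' The 20 standard residues in the column order of the `HMM` header line.
#' @export
HMM_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Transition score columns of an HMMER2 state line
#'
#' Order matches the save-file header `m->m m->i m->d i->m i->i d->m d->d
#' b->m m->e`. `BM` on row k is the begin-to-match entry score into match
#' state k; `ME` on row k is the match-to-end exit score out of state k.
#' @export
HMM_TRANSITIONS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD", "BM", "ME")

#' Special (position-invariant) transition names on the XT line
#' @export
HMM_XT_NAMES <- c("NB", "NN", "EC", "EJ", "CT", "CC", "JB", "JJ")

#' Construct a profile-HMM parameter set
#'
#' In-memory representation of an HMMER2-format profile HMM, sufficient to
#' reconstruct alignment log-odds scores and E-values. All scores are in
#' bits; impossible transitions/emissions are `-Inf`.
#'
#' @param name model identifier.
#' @param match_emission numeric K x 20 matrix of match-emission log-odds
#'   scores (bits), columns in `HMM_ALPHABET` order.
#' @param insert_emission numeric K x 20 matrix of insert-emission scores
#'   (bits). Row K is conventionally all `-Inf` (no insert state after the
#'   last match state).
#' @param transition numeric K x 9 matrix of transition scores (bits),
#'   columns in `HMM_TRANSITIONS` order.
#' @param xt named numeric vector of the 8 special transition scores
#'   (bits), names `HMM_XT_NAMES`.
#' @param nult numeric length-2 null-model transition scores (bits).
#' @param nule numeric length-20 null-model emission parameters (the NULE
#'   line, kept verbatim for round-tripping).
#' @param evd_mu,evd_lambda Gumbel extreme-value calibration; `NA` when the
#'   model file carries no EVD line (uncalibrated).
#' @param b_line numeric length-3 vector holding the special line
#'   between the transition header and state 1 (begin-state transitions);
#'   preserved verbatim for round-tripping.
#' @param map optional integer vector of alignment-map columns (MAP
#'   annotation), or `NULL`.
#'
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(name, match_emission, insert_emission, transition,
                      xt, nult, nule, evd_mu = NA_real_,
                      evd_lambda = NA_real_, b_line = c(0, -Inf, 0),
                      map = NULL) {
  m <- structure(
    list(name = as.character(name),
         length = nrow(match_emission),
         alphabet = HMM_ALPHABET,
         match_emission = match_emission,
         insert_emission = insert_emission,
         transition = transition,
         xt = xt, nult = nult, nule = nule,
         evd_mu = evd_mu, evd_lambda = evd_lambda,
         b_line = b_line, map = map),
    class = "hmm_model")
  validate_hmm_model(m)
}

validate_hmm_model <- function(m) {
  stopifnot(inherits(m, "hmm_model"))
  K <- m$length
  if (K < 1L) stop("model must have at least one match state")
  chk_mat <- function(x, nc, what) {
    if (!is.matrix(x) || nrow(x) != K || ncol(x) != nc)
      stop(sprintf("%s must be a %d x %d numeric matrix", what, K, nc))
    if (any(is.na(x)) || any(x == Inf))
      stop(sprintf("%s contains non-finite scores other than -Inf", what))
  }
  chk_mat(m$match_emission, 20L, "match_emission")
  chk_mat(m$insert_emission, 20L, "insert_emission")
  chk_mat(m$transition, 9L, "transition")
  if (length(m$xt) != 8L) stop("xt must hold 8 special transition scores")
  if (is.null(names(m$xt))) names(m$xt) <- HMM_XT_NAMES
  if (length(m$nult) != 2L) stop("nult must hold 2 scores")
  if (length(m$nule) != 20L) stop("nule must hold 20 parameters")
  if (!is.na(m$evd_lambda) && m$evd_lambda <= 0)
    stop("evd_lambda must be positive")
  colnames(m$match_emission) <- HMM_ALPHABET
  colnames(m$insert_emission) <- HMM_ALPHABET
  colnames(m$transition) <- HMM_TRANSITIONS
  m
}

#' Is the model EVD-calibrated?
#'
#' Model files written by `hmmconvert -2` lack an EVD line; such models
#' parse fine but E-value computations require explicit `(mu, lambda)`.
#' @param model an `hmm_model`.
#' @return `TRUE` when both Gumbel parameters are present.
#' @export
is_calibrated <- function(model) {
  !is.na(model$evd_mu) && !is.na(model$evd_lambda)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("Profile HMM '%s': %d match states\n", x$name, x$length))
  if (is_calibrated(x)) {
    cat(sprintf("  EVD calibration: mu = %.4f, lambda = %.4f\n",
                x$evd_mu, x$evd_lambda))
  } else {
    cat("  uncalibrated (no EVD line); supply mu/lambda for E-values\n")
  }
  cat(sprintf("  fixed score f = %.3f bits\n", fixed_score(x)))
  invisible(x)
}

# integer (1/1000-bit) field -> bits; '*' -> -Inf
score_from_field <- function(x) {
  out <- rep(NA_real_, length(x))
  star <- x == "*"
  out[star] <- -Inf
  out[!star] <- suppressWarnings(as.numeric(x[!star])) / 1000
  if (any(is.na(out)))
    stop("unparseable score field(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# bits -> integer field; -Inf -> '*'
score_to_field <- function(x) {
  if (any(is.na(x)) || any(x == Inf))
    stop("non-finite score that is not the -Inf sentinel")
  out <- rep("*", length(x))
  fin <- is.finite(x)
  out[fin] <- sprintf("%d", as.integer(round(x[fin] * 1000)))
  out
}

fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

#' Parse an HMMER2-format profile-HMM model
#'
#' Reads the ASCII HMMER2 save format (header `HMMER2.0`, including the
#' files produced by `hmmconvert -2` from HMMER3 models). Integer score
#' fields are converted to bits (divided by 1000); `*` becomes `-Inf`.
#'
#' @param text character vector of file lines, or a single string
#'   containing the whole file.
#' @return An `hmm_model`. Models without an EVD line are returned with
#'   `evd_mu`/`evd_lambda` set to `NA` (see [is_calibrated()]).
#' @seealso [read_hmmer2_model()] to read from a file path.
#' @export
parse_hmmer2_model <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!length(text) || !grepl("^HMMER2\\.0", text[1]))
    stop("not an HMMER2-format model: missing 'HMMER2.0' header")

  grab <- function(key) {
    i <- grep(paste0("^", key, "\\s"), text)
    if (!length(i)) return(NULL)
    sub(paste0("^", key, "\\s+"), "", text[i[1]])
  }
  name <- grab("NAME")
  leng <- as.integer(grab("LENG"))
  if (is.na(leng) || leng < 1L) stop("missing or invalid LENG line")

  xt_raw <- grab("XT")
  if (is.null(xt_raw))
    stop("incomplete model: no XT line (special transition scores)")
  xt <- stats::setNames(score_from_field(fields(xt_raw)), HMM_XT_NAMES)

  nult_raw <- grab("NULT")
  nule_raw <- grab("NULE")
  if (is.null(nult_raw) || is.null(nule_raw))
    stop("incomplete model: missing NULT/NULE null-model lines")
  nult <- score_from_field(fields(nult_raw))
  nule <- score_from_field(fields(nule_raw))

  evd_raw <- grab("EVD")
  evd_mu <- evd_lambda <- NA_real_
  if (!is.null(evd_raw)) {
    ev <- as.numeric(fields(evd_raw))
    if (length(ev) != 2L || any(is.na(ev))) stop("malformed EVD line")
    evd_mu <- ev[1]; evd_lambda <- ev[2]
    if (evd_lambda <= 0) stop("EVD lambda must be positive")
  }

  hmm_at <- grep("^HMM\\s", text)
  if (!length(hmm_at)) stop("missing HMM emission/transition block")
  map_on <- identical(grab("MAP"), "yes")

  # Body: header letters line, transition-name line, begin-state line,
  # then K triples (match / insert / transition), then '//'.
  body <- text[(hmm_at[1] + 2L):length(text)]
  body <- body[trimws(body) != "" & !grepl("^//", body)]
  b_line <- score_from_field(fields(body[1]))
  body <- body[-1]
  if (length(body) < 3L * leng)
    stop(sprintf("truncated emission block: expected %d state lines, got %d",
                 3L * leng, length(body)))

  me <- ie <- matrix(NA_real_, leng, 20L)
  tr <- matrix(NA_real_, leng, 9L)
  map <- if (map_on) integer(leng) else NULL
  for (k in seq_len(leng)) {
    ml <- fields(body[3L * (k - 1L) + 1L])
    il <- fields(body[3L * (k - 1L) + 2L])
    tl <- fields(body[3L * (k - 1L) + 3L])
    if (!identical(suppressWarnings(as.integer(ml[1])), k))
      stop(sprintf("parse error at state %d: match line is indexed '%s'",
                   k, ml[1]))
    if (length(ml) < 21L || length(il) < 21L || length(tl) < 10L)
      stop(sprintf("truncated emission block at state %d", k))
    me[k, ] <- score_from_field(ml[2:21])
    if (map_on) map[k] <- as.integer(ml[22])
    ie[k, ] <- score_from_field(il[2:21])
    tr[k, ] <- score_from_field(tl[2:10])
  }

  hmm_model(name = if (is.null(name)) "unnamed" else name,
            match_emission = me, insert_emission = ie, transition = tr,
            xt = xt, nult = nult, nule = nule,
            evd_mu = evd_mu, evd_lambda = evd_lambda,
            b_line = b_line, map = map)
}

#' @rdname parse_hmmer2_model
#' @param path path to an HMMER2 model file.
#' @export
read_hmmer2_model <- function(path) parse_hmmer2_model(readLines(path))

#' Write a profile HMM in HMMER2 ASCII format
#'
#' Emits a file that [parse_hmmer2_model()] round-trips exactly: bit
#' scores are re-scaled to 1/1000-bit integers and `-Inf` becomes `*`.
#'
#' @param model an `hmm_model`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return (invisibly) the character vector of file lines.
#' @export
write_hmmer2_model <- function(model, path = NULL) {
  model <- validate_hmm_model(model)
  f7 <- function(x) formatC(score_to_field(x), width = 7)
  out <- c(
    "HMMER2.0  [hmmdissect]",
    paste0("NAME  ", model$name),
    paste0("LENG  ", model$length),
    "ALPH  Amino",
    paste0("MAP   ", if (is.null(model$map)) "no" else "yes"),
    paste0("XT  ", paste(f7(model$xt), collapse = " ")),
    paste0("NULT", paste(f7(model$nult), collapse = " ")),
    paste0("NULE", paste(f7(model$nule), collapse = " ")))
  if (is_calibrated(model))
    out <- c(out, sprintf("EVD   %.6f  %.6f", model$evd_mu, model$evd_lambda))
  out <- c(out,
           paste0("HMM   ", paste(formatC(HMM_ALPHABET, width = 7),
                                  collapse = "")),
           paste0("      ", paste(formatC(tolower(sub("(.)(.)", "\\1->\\2",
                  HMM_TRANSITIONS)), width = 7), collapse = "")),
           paste0("      ", paste(f7(model$b_line), collapse = " ")))
  for (k in seq_len(model$length)) {
    mline <- paste0(formatC(k, width = 6), " ",
                    paste(f7(model$match_emission[k, ]), collapse = " "))
    if (!is.null(model$map))
      mline <- paste0(mline, " ", formatC(model$map[k], width = 6))
    out <- c(out, mline,
             paste0("     - ",
                    paste(f7(model$insert_emission[k, ]), collapse = " ")),
             paste0("     - ",
                    paste(f7(model$transition[k, ]), collapse = " ")))
  }
  out <- c(out, "//")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Position-invariant (fixed) score of an alignment
#'
#' Sum of the special transition scores a single-domain alignment always
#' incurs: N->B entry, E->C and C->T exit. Per-residue N->N/C->C flanking
#' terms and the J loop (multi-domain re-entry) are not included.
#'
#' @param model an `hmm_model`.
#' @return fixed score f in bits.
#' @export
fixed_score <- function(model) {
  unname(model$xt[["NB"]] + model$xt[["EC"]] + model$xt[["CT"]])
}
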