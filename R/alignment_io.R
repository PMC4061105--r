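# Multiple alignments, per-hit model-to-sequence alignment paths, DSSP
# annotations and low-complexity masks. Model coordinates are 1-based
# closed intervals over 1..K, matching HMMER match-state numbering.

GAP <- "-"

#' Construct a multiple alignment
#'
#' A light container for an aligned set of protein sequences: rows are
#' uppercased and the gap characters `.` and `-` are unified to `-`.
#'
#' @param rows character vector of aligned sequences (equal lengths).
#' @param ids sequence identifiers.
#' @return Object of class `msa` with elements `ids`, `rows` (character
#'   vector), `mat` (M x N single-character matrix), `n_seq`, `n_col`.
#' @export
msa <- function(rows, ids = NULL) {
  if (!length(rows)) stop("alignment must contain at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  rows <- toupper(gsub(".", GAP, rows, fixed = TRUE))
  n <- unique(nchar(rows))
  if (length(n) != 1L) {
    bad <- ids[nchar(rows) != nchar(rows)[1]][1]
    stop("ragged alignment: row '", bad, "' differs in length")
  }
  mat <- matrix(unlist(strsplit(rows, "")), nrow = length(rows),
                byrow = TRUE, dimnames = list(ids, NULL))
  structure(list(ids = ids, rows = rows, mat = mat,
                 n_seq = length(rows), n_col = n),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              x$n_seq, x$n_col))
  invisible(x)
}

#' Read a seed multiple alignment
#'
#' Reads Stockholm or aligned-FASTA files (format auto-detected from the
#' first line) via Biostrings, then normalises case and gap symbols.
#'
#' @param path file path.
#' @return an [msa] object.
#' @export
read_stockholm <- function(path) {
  first <- readLines(path, n = 1L)
  fmt <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  aln <- Biostrings::readAAMultipleAlignment(path, format = fmt)
  rows <- as.character(Biostrings::unmasked(aln))
  msa(unname(rows), ids = names(rows))
}

#' Write a multiple alignment in Stockholm format
#'
#' @param aln an [msa].
#' @param path optional output path.
#' @return (invisibly) the file lines.
#' @export
write_stockholm <- function(aln, path = NULL) {
  w <- max(nchar(aln$ids)) + 2L
  out <- c("# STOCKHOLM 1.0",
           sprintf("%-*s%s", w, aln$ids, aln$rows), "//")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Construct a model-to-sequence alignment path
#'
#' An ordered list of steps through the profile HMM for one hit, possibly
#' split into several fragments (HMMER3-style local alignments). MATCH and
#' DELETE steps carry a model position; INSERT steps carry the model
#' position of the last MATCH/DELETE state visited (their anchor) but do
#' not advance the model. MATCH and INSERT steps carry a sequence
#' position; DELETE steps do not.
#'
#' @param steps data frame with columns `fragment` (integer), `state`
#'   (`"M"`, `"I"` or `"D"`), `model_pos`, `seq_pos`.
#' @param hit_id sequence identifier of the hit.
#' @param engine free-form tag of the search engine that produced the
#'   alignment (e.g. `"hmmer2"`, `"hmmer3"`).
#' @return Object of class `alignment_path` (the validated data frame
#'   with attributes `hit_id` and `engine`).
#' @export
alignment_path <- function(steps, hit_id, engine = "unknown") {
  stopifnot(is.data.frame(steps),
            all(c("fragment", "state", "model_pos", "seq_pos")
                %in% names(steps)))
  if (!all(steps$state %in% c("M", "I", "D")))
    stop("state must be one of M, I, D")
  if (any(is.na(steps$seq_pos[steps$state %in% c("M", "I")])))
    stop("MATCH/INSERT steps must carry a sequence position")
  if (!all(is.na(steps$seq_pos[steps$state == "D"])))
    stop("DELETE steps must not carry a sequence position")
  for (f in unique(steps$fragment)) {
    mp <- steps$model_pos[steps$fragment == f & steps$state != "I"]
    if (any(diff(mp) <= 0))
      stop("model position must strictly increase over MATCH/DELETE steps")
  }
  structure(steps, class = c("alignment_path", "data.frame"),
            hit_id = hit_id, engine = engine)
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf("Alignment path for hit '%s' (%s): %d steps, %d fragment(s)\n",
              attr(x, "hit_id"), attr(x, "engine"), nrow(x),
              length(unique(x$fragment))))
  invisible(x)
}

# walk one aligned fragment given the model line, target line and the
# model/sequence start coordinates; returns a step data frame
walk_fragment <- function(model_str, target_str, model_from, seq_from,
                          fragment) {
  mc <- strsplit(model_str, "")[[1]]
  tc <- strsplit(target_str, "")[[1]]
  if (length(mc) != length(tc))
    stop("parse error: model and target alignment lines differ in length")
  k <- model_from - 1L
  s <- seq_from - 1L
  state <- character(0); mp <- integer(0); sp <- integer(0)
  for (i in seq_along(mc)) {
    ins <- mc[i] %in% c(".", "*", "<", ">")  # non-consensus columns
    if (mc[i] == ".") {            # insert column
      s <- s + 1L
      state <- c(state, "I"); mp <- c(mp, max(k, 1L)); sp <- c(sp, s)
    } else if (tc[i] == "-") {     # delete
      k <- k + 1L
      state <- c(state, "D"); mp <- c(mp, k); sp <- c(sp, NA_integer_)
    } else {                       # match
      k <- k + 1L; s <- s + 1L
      state <- c(state, "M"); mp <- c(mp, k); sp <- c(sp, s)
    }
  }
  data.frame(fragment = fragment, state = state, model_pos = mp,
             seq_pos = sp)
}

#' Parse hmmsearch plain-text domain alignments
#'
#' Extracts one [alignment_path] per target sequence from the alignment
#' section of `hmmsearch` output. Both engine layouts are supported:
#' \describe{
#'   \item{HMMER3}{`>> target` sections with `== domain N` blocks whose
#'     model line carries explicit model coordinates; `.` in the model
#'     line marks insert columns, `-` in the target line deletions.
#'     Several domain blocks for one target become fragments of a single
#'     path.}
#'   \item{HMMER2}{`target: domain i of n, from A to B` headers followed
#'     by a `*->...<-*` model consensus line; the complete (glocal) model
#'     is assumed, so model coordinates start at 1.}
#' }
#'
#' @param text character vector of output lines, a single string, or a
#'   file path.
#' @param model the `hmm_model` searched (used for validation only).
#' @param engine `"auto"` (default), `"hmmer2"` or `"hmmer3"`.
#' @return list of [alignment_path] objects, one per hit sequence.
#' @export
parse_hmmsearch_alignment <- function(text, model = NULL,
                                      engine = c("auto", "hmmer3", "hmmer2")) {
  engine <- match.arg(engine)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (engine == "auto") {
    engine <- if (any(grepl("^>>\\s", text))) "hmmer3" else "hmmer2"
  }
  paths <- if (engine == "hmmer3") parse_h3_blocks(text)
           else parse_h2_blocks(text)
  if (!is.null(model)) {
    for (p in paths) {
      if (any(p$model_pos > model$length, na.rm = TRUE))
        stop("alignment visits model position beyond model length")
    }
  }
  paths
}

parse_h3_blocks <- function(text) {
  sec <- grep("^>>\\s", text)
  if (!length(sec)) stop("no '>> target' sections found")
  ends <- c(sec[-1] - 1L, length(text))
  out <- list()
  for (i in seq_along(sec)) {
    hit_id <- fields(sub("^>>\\s+", "", text[sec[i]]))[1]
    block <- text[sec[i]:ends[i]]
    dom <- grep("^\\s*== domain", block)
    if (!length(dom)) next
    dom_ends <- c(dom[-1] - 1L, length(block))
    steps <- NULL
    for (d in seq_along(dom)) {
      sub_blk <- block[dom[d]:dom_ends[d]]
      st <- parse_h3_domain(sub_blk, hit_id)
      st$fragment <- d
      steps <- rbind(steps, st)
    }
    out[[hit_id]] <- alignment_path(steps, hit_id, engine = "hmmer3")
  }
  out
}

# one '== domain' block: stanzas of (model line, match line, target line,
# PP line); long alignments wrap into several stanzas
parse_h3_domain <- function(block, hit_id) {
  steps <- NULL
  i <- 2L
  while (i <= length(block)) {
    f <- fields(block[i])
    # model line: <qname> <from> <aln> <to>
    if (length(f) == 4L && !is.na(suppressWarnings(as.integer(f[2]))) &&
        !is.na(suppressWarnings(as.integer(f[4])))) {
      tl <- NULL
      for (j in (i + 1L):min(i + 3L, length(block))) {
        ft <- fields(block[j])
        if (length(ft) == 4L && ft[1] == hit_id) { tl <- ft; i <- j; break }
      }
      if (is.null(tl))
        stop("parse error: no target line for model line '", block[i], "'")
      steps <- rbind(steps,
                     walk_fragment(f[3], tl[3], as.integer(f[2]),
                                   as.integer(tl[2]), fragment = 1L))
    }
    i <- i + 1L
  }
  if (is.null(steps)) stop("empty domain alignment block")
  steps
}

parse_h2_blocks <- function(text) {
  hd <- grep("^\\S+: domain \\d+ of \\d+, from", text)
  if (!length(hd)) stop("no HMMER2 domain alignment headers found")
  ends <- c(hd[-1] - 1L, length(text))
  out <- list()
  frag_of <- list()
  for (i in seq_along(hd)) {
    h <- text[hd[i]]
    hit_id <- sub(":.*$", "", h)
    seq_from <- as.integer(sub("^.*from (\\d+) to.*$", "\\1", h))
    block <- text[(hd[i] + 1L):ends[i]]
    # stanzas: model line (indented, may carry *-> / <-*), match line,
    # target line '<id> <from> <aln> <to>'
    mdl <- character(0); tgt <- character(0)
    j <- 1L
    while (j <= length(block)) {
      f <- fields(block[j])
      if (length(f) == 4L && f[1] == hit_id &&
          !is.na(suppressWarnings(as.integer(f[2])))) {
        tgt <- c(tgt, f[3])
        mdl <- c(mdl, fields(block[j - 2L])[1])
      }
      j <- j + 1L
    }
    if (!length(tgt)) next
    m <- paste(mdl, collapse = "")
    m <- gsub("\\*->|<-\\*", "", m)
    frag <- length(frag_of[[hit_id]] %||% integer(0)) + 1L
    st <- walk_fragment(m, paste(tgt, collapse = ""), 1L, seq_from,
                        fragment = frag)
    frag_of[[hit_id]] <- c(frag_of[[hit_id]], frag)
    out[[hit_id]] <- rbind(out[[hit_id]], st)
  }
  lapply(stats::setNames(names(out), names(out)), function(id)
    alignment_path(out[[id]], id, engine = "hmmer2"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write explicit alignment paths as TSV
#'
#' Plain tab-separated representation (`hit_id`, `engine`, `fragment`,
#' `state`, `model_pos`, `seq_pos`) that bypasses hmmsearch text parsing.
#'
#' @param path file path.
#' @return list of [alignment_path] objects (one per `hit_id`).
#' @export
read_path_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("hit_id", "engine", "fragment", "state", "model_pos", "seq_pos")
  if (!all(need %in% names(df)))
    stop("path TSV must have columns: ", paste(need, collapse = ", "))
  cols <- intersect(c("fragment", "state", "model_pos", "seq_pos",
                      "residue"), names(df))
  lapply(split(df, df$hit_id), function(d)
    alignment_path(d[cols], hit_id = d$hit_id[1], engine = d$engine[1]))
}

#' @rdname read_path_tsv
#' @param paths list of [alignment_path] objects.
#' @export
write_path_tsv <- function(paths, path) {
  if (inherits(paths, "alignment_path")) paths <- list(paths)
  df <- do.call(rbind, lapply(paths, function(p)
    cbind(hit_id = attr(p, "hit_id"), engine = attr(p, "engine"),
          as.data.frame(p))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read secondary-structure labels from a DSSP file
#'
#' Minimal fixed-column reader for the classic DSSP output format:
#' residue number, chain, amino acid and the one-letter secondary
#' structure code are extracted from the per-residue table. A blank
#' structure code (loop) is returned as `" "`.
#'
#' @param path DSSP file path.
#' @param chain optional chain identifier to filter on.
#' @return named character vector of structure codes, names = residue
#'   numbers (as given in the file).
#' @export
read_dssp <- function(path, chain = NULL) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file: per-residue header not found")
  body <- lines[(hdr[1] + 1L):length(lines)]
  resnum <- suppressWarnings(as.integer(substr(body, 6, 10)))
  ch <- trimws(substr(body, 12, 12))
  ss <- substr(body, 17, 17)
  keep <- !is.na(resnum)              # skips chain-break '!' records
  if (!is.null(chain)) keep <- keep & ch == chain
  stats::setNames(ss[keep], resnum[keep])
}

#' Project per-residue DSSP labels onto model coordinates
#'
#' Each MATCH position of the path receives the DSSP label of its aligned
#' hit residue; DELETE positions and model positions the (local) path
#' never visits receive the gap marker `-`. INSERT steps carry no model
#' position and are dropped.
#'
#' @param dssp_labels named character vector from [read_dssp()] (names
#'   are hit-sequence residue numbers), or an unnamed vector indexed by
#'   position.
#' @param path an [alignment_path] whose `seq_pos` uses the same residue
#'   numbering.
#' @param model_length number of match states K; defaults to the largest
#'   model position on the path.
#' @return Object of class `residue_annotation`: character vector of
#'   length K over the DSSP alphabet plus `" "` (loop) and `-` (gap),
#'   with attribute `source = "dssp"`.
#' @export
project_dssp_to_model <- function(dssp_labels, path,
                                  model_length = max(path$model_pos)) {
  if (is.null(names(dssp_labels)))
    names(dssp_labels) <- seq_along(dssp_labels)
  ann <- rep(GAP, model_length)
  mm <- path[path$state == "M", ]
  miss <- setdiff(as.character(mm$seq_pos), names(dssp_labels))
  if (length(miss))
    stop("path references residue(s) absent from the DSSP labels: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  ann[mm$model_pos] <- unname(dssp_labels[as.character(mm$seq_pos)])
  structure(ann, class = "residue_annotation", source = "dssp")
}
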