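.gapListOf <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  r <- rle(ch == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gl <- cbind(start = starts[r$values], length = r$lengths[r$values])
  storage.mode(gl) <- "integer"
  gl
}

#' Create a sequence handle
#'
#' Builds a \linkS4class{SequenceHandle} from a one-letter-code string.
#' \code{"-"} marks gaps; \code{"."} is accepted on input and normalised
#' to \code{"-"}; lower case is stored upper case.  Any character outside
#' \code{A-Z}, \code{-}, \code{.} is an error.  The gap list (run-length
#' encoding of the gap positions) is built once and kept consistent by
#' all editing operations.
#'
#' @param name sequence name.
#' @param string the sequence.
#' @param offset number of residues of the full molecule preceding this
#'   sequence; the first non-gap character is residue \code{offset + 1}.
#' @return a \linkS4class{SequenceHandle}.
#' @examples
#' s <- createSequence("s1", "AB--C")
#' gapList(s)            # one run: start 3, length 2
#' posToResidueIndex(s, 5)  # 3
#' @export
createSequence <- function(name, string, offset = 0L) {
  string <- toupper(gsub(".", "-", string, fixed = TRUE))
  bad <- regmatches(string, regexpr("[^A-Z-]", string))
  if (length(bad) && nzchar(bad))
    stop("illegal sequence character '", bad, "' in sequence ", name)
  new("SequenceHandle", name = as.character(name), seq = string,
      offset = as.integer(offset), gapList = .gapListOf(string),
      attached = list())
}

#' Sequence accessors
#' @param x a \linkS4class{SequenceHandle}.
#' @name sequenceAccessors
NULL

#' @rdname sequenceAccessors
#' @export
sequenceString <- function(x) x@seq

#' @rdname sequenceAccessors
#' @export
sequenceName <- function(x) x@name

#' @rdname sequenceAccessors
#' @export
sequenceOffset <- function(x) x@offset

#' @rdname sequenceAccessors
#' @export
gapList <- function(x) x@gapList

#' @rdname sequenceAccessors
#' @export
nonGapCount <- function(x) nchar(x@seq) - sum(x@gapList[, "length"])

#' Map alignment positions to residue indices and back
#'
#' \code{posToResidueIndex} maps alignment position \code{pos} (1-based)
#' to the index of the residue at that position:
#' \code{offset + pos - gaps_before(pos)}, or \code{NA} when the position
#' is a gap.  \code{residueIndexToPos} is its inverse on non-gap
#' positions.  Both traverse the gap list, not the sequence, so their
#' cost is proportional to the number of gap runs -- with \code{counted =
#' TRUE} they return the number of gap-list entries inspected alongside
#' the result, which test suites use to verify that bound.
#'
#' @param seq a \linkS4class{SequenceHandle}.
#' @param pos alignment position, 1-based.
#' @param index residue index (\code{offset + 1} ... \code{offset +
#'   nonGapCount}).
#' @param counted return \code{list(value, inspected)} instead of the
#'   bare value.
#' @return integer position/index (or \code{NA} for a gap position), or
#'   the counted list form.
#' @export
posToResidueIndex <- function(seq, pos, counted = FALSE) {
  n <- nchar(seq@seq)
  if (!is.numeric(pos) || length(pos) != 1L || pos < 1L || pos > n)
    stop("alignment position out of range [1, ", n, "]")
  pos <- as.integer(pos)
  gl <- seq@gapList
  inspected <- 0L
  gapsBefore <- 0L
  isGap <- FALSE
  for (k in seq_len(nrow(gl))) {
    inspected <- inspected + 1L
    s <- gl[k, 1L]; len <- gl[k, 2L]
    if (s > pos) break
    if (pos < s + len) { isGap <- TRUE; break }
    gapsBefore <- gapsBefore + len
  }
  val <- if (isGap) NA_integer_
         else unname(seq@offset + pos - gapsBefore)
  if (counted) list(value = val, inspected = inspected) else val
}

#' @rdname posToResidueIndex
#' @export
residueIndexToPos <- function(seq, index, counted = FALSE) {
  ng <- nonGapCount(seq)
  if (!is.numeric(index) || length(index) != 1L ||
      index < seq@offset + 1L || index > seq@offset + ng)
    stop("residue index out of range [", seq@offset + 1L, ", ",
         seq@offset + ng, "]")
  pos <- as.integer(index) - seq@offset
  gl <- seq@gapList
  inspected <- 0L
  for (k in seq_len(nrow(gl))) {
    inspected <- inspected + 1L
    if (gl[k, 1L] > pos) break
    pos <- unname(pos + gl[k, 2L])
  }
  if (counted) list(value = pos, inspected = inspected) else pos
}

#' Attach a structure to a sequence
#'
#' Links an \linkS4class{EntityView} to a sequence, relating positions in
#' the (possibly gapped) sequence to residues of the structure.  The view
#' must have exactly one residue per non-gap character and the residue
#' one-letter codes must match position-wise (\code{X} matches anything,
#' in either direction).  After attachment, \code{residueAtPos} resolves
#' an alignment position to the corresponding residue of the view
#' (\code{NA} row for gap positions).
#'
#' @param seq a \linkS4class{SequenceHandle}.
#' @param view an \linkS4class{EntityView} whose residues carry one-letter
#'   codes (run a connectivity processor first).
#' @return \code{attachView}: the updated sequence handle;
#'   \code{attachedView}: the attached view or \code{NULL};
#'   \code{residueAtPos}: a one-row data.frame of the residue table, or
#'   \code{NULL} for a gap position.
#' @export
attachView <- function(seq, view) {
  stopifnot(is(view, "EntityView"))
  res <- residues(view)
  ng <- nonGapCount(seq)
  if (nrow(res) != ng)
    stop("attach failed: view has ", nrow(res), " residue(s), sequence has ",
         ng, " non-gap character(s)")
  chars <- strsplit(seq@seq, "", fixed = TRUE)[[1]]
  codes <- chars[chars != "-"]
  mism <- which(codes != res$olc & codes != "X" & res$olc != "X")
  if (length(mism)) {
    k <- mism[1]
    pos <- which(chars != "-")[k]
    stop(sprintf(
      "attach failed: sequence has '%s' but structure residue %s.%d is '%s' (alignment position %d)",
      codes[k], res$chain[k], res$resnum[k], res$olc[k], pos))
  }
  seq@attached <- list(view)
  seq
}

#' @rdname attachView
#' @export
attachedView <- function(seq)
  if (length(seq@attached)) seq@attached[[1]] else NULL

#' @rdname attachView
#' @param pos alignment position, 1-based.
#' @export
residueAtPos <- function(seq, pos) {
  v <- attachedView(seq)
  if (is.null(v)) stop("sequence has no attached structure")
  idx <- posToResidueIndex(seq, pos)
  if (is.na(idx)) return(NULL)
  residues(v)[idx - seq@offset, , drop = FALSE]
}

# ---- alignments --------------------------------------------------------

#' Create an alignment
#'
#' @param ... \linkS4class{SequenceHandle}s, or named strings
#'   (\code{createAlignment(s1 = "AB-C", s2 = "ABDC")}); all must have
#'   equal length.
#' @return an \linkS4class{AlignmentHandle}.
#' @export
createAlignment <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) &&
      !is(args[[1]], "SequenceHandle")) args <- args[[1]]
  seqs <- lapply(seq_along(args), function(i) {
    a <- args[[i]]
    if (is(a, "SequenceHandle")) a
    else createSequence(if (!is.null(names(args)) && nzchar(names(args)[i]))
      names(args)[i] else paste0("seq", i), as.character(a))
  })
  new("AlignmentHandle", sequences = seqs)
}

#' Alignment accessors and column editing
#'
#' The alignment interface is column-oriented.  \code{alignmentColumn}
#' extracts column \code{pos} as a character vector;
#' \code{insertGapColumn} inserts an all-gap column before position
#' \code{pos} (\code{pos = length + 1} appends); \code{removeColumn}
#' deletes column \code{pos} and refuses -- unless \code{force = TRUE} --
#' when the column contains non-gap characters.  All edits keep the
#' sequences at equal length and their gap lists consistent.
#'
#' @param aln an \linkS4class{AlignmentHandle}.
#' @param pos column position.
#' @param force remove a column even if it holds residues.
#' @return edited \linkS4class{AlignmentHandle} (edits), list of
#'   \linkS4class{SequenceHandle} (\code{sequences}), integer
#'   (\code{alignmentLength}), character vector (\code{alignmentColumn}).
#' @name alignmentOps
NULL

#' @rdname alignmentOps
#' @export
sequences <- function(aln) aln@sequences

#' @rdname alignmentOps
#' @export
alignmentLength <- function(aln) nchar(aln@sequences[[1]]@seq)

#' @rdname alignmentOps
#' @export
alignmentColumn <- function(aln, pos) {
  n <- alignmentLength(aln)
  if (pos < 1L || pos > n) stop("column out of range [1, ", n, "]")
  vapply(aln@sequences, function(s) substr(s@seq, pos, pos), character(1))
}

.reSeq <- function(s, newString) {
  s@seq <- newString
  s@gapList <- .gapListOf(newString)
  s
}

#' @rdname alignmentOps
#' @export
insertGapColumn <- function(aln, pos) {
  n <- alignmentLength(aln)
  if (pos < 1L || pos > n + 1L) stop("column out of range [1, ", n + 1L, "]")
  aln@sequences <- lapply(aln@sequences, function(s)
    .reSeq(s, paste0(substr(s@seq, 1, pos - 1L), "-",
                     substr(s@seq, pos, n))))
  validObject(aln)
  aln
}

#' @rdname alignmentOps
#' @export
removeColumn <- function(aln, pos, force = FALSE) {
  n <- alignmentLength(aln)
  if (pos < 1L || pos > n) stop("column out of range [1, ", n, "]")
  col <- alignmentColumn(aln, pos)
  if (!force && any(col != "-"))
    stop("column ", pos, " contains residues; use force = TRUE to remove it")
  aln@sequences <- lapply(aln@sequences, function(s)
    .reSeq(s, paste0(substr(s@seq, 1, pos - 1L), substr(s@seq, pos + 1L, n))))
  validObject(aln)
  aln
}

# ---- sequence & alignment file I/O ------------------------------------

.checkDupNames <- function(nms, what)
  if (anyDuplicated(nms)) stop("duplicate sequence name in ", what, ": ",
                               nms[duplicated(nms)][1])

#' Sequence and alignment file input/output
#'
#' \code{readSequences} imports FASTA, ClustalW (\code{.aln}) or PIR
#' files into a \linkS4class{SequenceList}; \code{readAlignment} does the
#' same and additionally requires equal lengths, returning an
#' \linkS4class{AlignmentHandle}.  Export is supported for FASTA and PIR.
#' ClustalW blocks are concatenated per sequence in first-block order;
#' ragged blocks are an error.  The PIR two-letter header type (e.g.
#' \code{P1}) is preserved on round trip (reader stores it, writer reuses
#' it; default \code{P1}).
#'
#' @param path file path.
#' @param format \code{"fasta"}, \code{"clustal"} or \code{"pir"};
#'   default guesses from the extension (\code{.aln} = clustal,
#'   \code{.pir} = pir, otherwise fasta).
#' @param x a \linkS4class{SequenceList}, \linkS4class{AlignmentHandle},
#'   or list of \linkS4class{SequenceHandle}s.
#' @param pirTypes character vector of PIR types recycled over sequences.
#' @return \code{readSequences}: \linkS4class{SequenceList} (with
#'   attribute-free per-sequence PIR types retrievable via
#'   \code{pirTypes()}); \code{readAlignment}:
#'   \linkS4class{AlignmentHandle}; writers return the path invisibly.
#' @name sequenceIO
NULL

.guessSeqFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "aln") "clustal" else if (ext == "pir") "pir" else "fasta"
}

.pirTypeCache <- new.env(parent = emptyenv())

#' @rdname sequenceIO
#' @export
readSequences <- function(path, format = .guessSeqFormat(path)) {
  format <- match.arg(format, c("fasta", "clustal", "pir"))
  seqs <- switch(format,
    fasta = {
      set <- Biostrings::readBStringSet(path)
      .checkDupNames(names(set), path)
      lapply(seq_along(set), function(i)
        createSequence(sub("\\s.*$", "", names(set)[i]),
                       as.character(set[[i]])))
    },
    clustal = .readClustal(path),
    pir = .readPir(path))
  new("SequenceList", sequences = seqs)
}

#' @rdname sequenceIO
#' @export
readAlignment <- function(path, format = .guessSeqFormat(path)) {
  sl <- readSequences(path, format)
  new("AlignmentHandle", sequences = sl@sequences)
}

.readClustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[1]))
    stop("not a ClustalW file (missing CLUSTAL header): ", path)
  lines <- lines[-1]
  # split into blocks at blank lines; drop conservation lines (leading ws)
  blockId <- cumsum(!nzchar(trimws(lines)))
  blocks <- split(lines, blockId)
  order <- NULL; parts <- list()
  for (blk in blocks) {
    blk <- blk[nzchar(trimws(blk)) & !grepl("^\\s", blk)]
    if (!length(blk)) next
    nms <- character(); chunks <- character()
    for (l in blk) {
      m <- regmatches(l, regexec("^(\\S+)\\s+([A-Za-z.-]+)\\s*\\d*$", l))[[1]]
      if (length(m) != 3L) stop("malformed ClustalW line: ", l)
      nms <- c(nms, m[2]); chunks <- c(chunks, m[3])
    }
    if (anyDuplicated(nms))
      stop("duplicate sequence name within a ClustalW block: ",
           nms[duplicated(nms)][1])
    if (is.null(order)) {
      order <- nms
      parts <- stats::setNames(as.list(chunks), nms)
    } else {
      if (!setequal(nms, order))
        stop("ragged ClustalW blocks: block sequence sets differ in ", path)
      for (k in seq_along(nms))
        parts[[nms[k]]] <- c(parts[[nms[k]]], chunks[k])
    }
  }
  if (is.null(order)) stop("empty ClustalW file: ", path)
  strs <- vapply(order, function(nm) paste(parts[[nm]], collapse = ""),
                 character(1))
  if (length(unique(nchar(strs))) > 1L)
    stop("ragged ClustalW blocks: concatenated lengths differ in ", path)
  lapply(order, function(nm) createSequence(nm, strs[[nm]]))
}

.readPir <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>..;", lines)
  if (!length(starts)) stop("not a PIR file (no '>Xn;' header): ", path)
  bounds <- c(starts, length(lines) + 1L)
  types <- character()
  seqs <- list()
  for (k in seq_along(starts)) {
    hdr <- lines[starts[k]]
    type <- substr(hdr, 2, 3)
    nm <- sub("^>..;", "", hdr)
    body <- lines[(starts[k] + 2L):(bounds[k + 1L] - 1L)]  # skip description
    s <- gsub("[[:space:]]", "", paste(body, collapse = ""))
    if (!grepl("\\*$", s))
      stop("PIR entry '", nm, "' lacks the terminating '*'")
    s <- sub("\\*$", "", s)
    types <- c(types, type)
    seqs[[k]] <- createSequence(nm, s)
  }
  .checkDupNames(vapply(seqs, sequenceName, character(1)), path)
  assign(normalizePath(path), types, envir = .pirTypeCache)
  attr(seqs, "pirTypes") <- types
  seqs
}

.seqListOf <- function(x) {
  if (is(x, "SequenceList") || is(x, "AlignmentHandle")) x@sequences
  else if (is(x, "SequenceHandle")) list(x)
  else if (is.list(x)) x
  else stop("expected sequences")
}

#' @rdname sequenceIO
#' @export
writeFasta <- function(x, path) {
  seqs <- .seqListOf(x)
  .checkDupNames(vapply(seqs, sequenceName, character(1)), "output")
  con <- file(path, "w"); on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s@name), con)
    writeLines(substring(s@seq, seq(1, nchar(s@seq), 60),
                         pmin(seq(1, nchar(s@seq), 60) + 59, nchar(s@seq))),
               con)
  }
  invisible(path)
}

#' @rdname sequenceIO
#' @export
writePir <- function(x, path, pirTypes = "P1") {
  seqs <- .seqListOf(x)
  pirTypes <- rep_len(pirTypes, length(seqs))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    writeLines(c(paste0(">", pirTypes[i], ";", s@name),
                 paste0("sequence ", s@name)), con)
    body <- substring(paste0(s@seq, "*"),
                      seq(1, nchar(s@seq) + 1L, 60),
                      pmin(seq(1, nchar(s@seq) + 1L, 60) + 59,
                           nchar(s@seq) + 1L))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname sequenceIO
#' @export
pirTypes <- function(path) {
  p <- normalizePath(path)
  if (exists(p, envir = .pirTypeCache, inherits = FALSE))
    get(p, envir = .pirTypeCache, inherits = FALSE)
  else attr(.readPir(path), "pirTypes")
}

setMethod("show", "SequenceList", function(object) {
  cat(sprintf("SequenceList: %d sequence(s)\n", length(object@sequences)))
  for (s in object@sequences)
    cat(sprintf("  %-12s (%d)\n", s@name, nchar(s@seq)))
})
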