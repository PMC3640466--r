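# Pairwise alignment by affine-gap dynamic programming (the three-matrix
# Gotoh formulation) and column conservation scoring.

#' Scoring schemes for pairwise alignment
#'
#' A scoring scheme bundles a symmetric substitution matrix with affine
#' gap penalties: a gap of length L costs \code{gapOpen + (L - 1) *
#' gapExtend} (both negative; \code{gapExtend >= gapOpen}).  The default
#' scheme is BLOSUM62 with gap open -10 and extend -1.
#' \code{readSubstitutionMatrix} parses NCBI-format matrix files
#' (\code{#} comments, a header row of residue letters, one labelled row
#' per residue).
#'
#' @param matrix substitution matrix with matching row/column names.
#' @param gapOpen,gapExtend gap penalties (negative).
#' @param match,mismatch scores for the uniform toy matrix over A-Z.
#' @param path NCBI-format matrix file.
#' @return a scoring scheme (list with elements \code{matrix},
#'   \code{gapOpen}, \code{gapExtend}).
#' @export
scoringScheme <- function(matrix, gapOpen = -10, gapExtend = -1) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have matching row/column names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gapOpen > 0 || gapExtend > 0) stop("gap penalties must be <= 0")
  if (gapExtend < gapOpen)
    stop("gapExtend must be >= gapOpen (extension is the milder penalty)")
  list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend)
}

.blosumCache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosumCache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosumCache$m <- e$BLOSUM62
  }
  .blosumCache$m
}

#' @rdname scoringScheme
#' @export
defaultScoringScheme <- function(gapOpen = -10, gapExtend = -1)
  scoringScheme(.blosum62(), gapOpen, gapExtend)

#' @rdname scoringScheme
#' @export
uniformScoringScheme <- function(match = 1, mismatch = -1, gapOpen = -2,
                                 gapExtend = -1) {
  m <- matrix(mismatch, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(m) <- match
  scoringScheme(m, gapOpen, gapExtend)
}

#' @rdname scoringScheme
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- grep("^\\s*#", readLines(path, warn = FALSE), value = TRUE,
                invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(rows, `[`, character(1), 1)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(m) <- list(rn, cols)
  m[rn, rn, drop = FALSE]
}

.subScore <- function(scheme, a, b) {
  m <- scheme$matrix
  if (!all(c(a, b) %in% rownames(m)))
    stop("residue(s) missing from the substitution matrix: ",
         paste(setdiff(c(a, b), rownames(m)), collapse = ", "))
  m[a, b]
}

.checkAlignInput <- function(s) {
  if (!nchar(s)) stop("cannot align an empty sequence")
  if (grepl("-", s, fixed = TRUE))
    stop("input sequences must be ungapped")
}

# shared Gotoh engine; local = floor M at 0 and trace from the best cell
.gotoh <- function(a, b, scheme, local) {
  .checkAlignInput(a); .checkAlignInput(b)
  A <- strsplit(toupper(a), "")[[1]]; B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  go <- scheme$gapOpen; ge <- scheme$gapExtend
  S <- scheme$matrix[A, B, drop = FALSE]
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # ends with A[i] over a gap
  Iy <- matrix(NEG, n + 1, m + 1)  # ends with a gap over B[j]
  M[1, 1] <- 0
  if (!local) {
    if (n) Ix[2:(n + 1), 1] <- go + (0:(n - 1)) * ge
    if (m) Iy[1, 2:(m + 1)] <- go + (0:(m - 1)) * ge
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      best <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      v <- best + S[i - 1, j - 1]
      M[i, j] <- if (local) max(0, v) else v
      Ix[i, j] <- max(M[i - 1, j] + go, Ix[i - 1, j] + ge)
      Iy[i, j] <- max(M[i, j - 1] + go, Iy[i, j - 1] + ge)
    }
  }
  list(M = M, Ix = Ix, Iy = Iy, A = A, B = B, S = S, go = go, ge = ge)
}

# traceback; tie-break: diagonal (M), then up (Ix), then left (Iy)
.traceback <- function(d, i, j, state, local) {
  outA <- character(); outB <- character()
  eq <- function(x, y) abs(x - y) <= 1e-9
  while (TRUE) {
    if (local && state == "M" && eq(d$M[i, j], 0)) break
    if (!local && i == 1L && j == 1L) break
    if (state == "M") {
      v <- d$M[i, j] - d$S[i - 1, j - 1]
      outA <- c(d$A[i - 1], outA); outB <- c(d$B[j - 1], outB)
      i <- i - 1L; j <- j - 1L
      state <- if (eq(v, d$M[i, j])) "M"
               else if (eq(v, d$Ix[i, j])) "Ix" else "Iy"
    } else if (state == "Ix") {
      outA <- c(d$A[i - 1], outA); outB <- c("-", outB)
      v <- d$Ix[i, j]; i <- i - 1L
      state <- if (eq(v, d$M[i, j] + d$go)) "M" else "Ix"
    } else {
      outA <- c("-", outA); outB <- c(d$B[j - 1], outB)
      v <- d$Iy[i, j]; j <- j - 1L
      state <- if (eq(v, d$M[i, j] + d$go)) "M" else "Iy"
    }
  }
  list(a = paste(outA, collapse = ""), b = paste(outB, collapse = ""),
       i = i, j = j)
}

.alignResult <- function(sa, sb, nameA, nameB, score, offA = 0L, offB = 0L) {
  aln <- new("AlignmentHandle", sequences = list(
    createSequence(nameA, sa, offset = offA),
    createSequence(nameB, sb, offset = offB)))
  new("PairwiseAlignmentResult", alignment = aln, score = as.numeric(score),
      identity = sequenceIdentity(aln))
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Aligns two ungapped sequences end to end under the Gotoh three-matrix
#' affine-gap recursion; terminal gaps are penalised.  Traceback ties
#' prefer the diagonal, then the gap in the second sequence, making the
#' emitted alignment deterministic; it always re-scores to the reported
#' optimal score.
#'
#' @param s1,s2 sequences (strings or \linkS4class{SequenceHandle}s).
#' @param scheme a scoring scheme, see \code{\link{scoringScheme}}.
#' @return a \linkS4class{PairwiseAlignmentResult}.
#' @examples
#' r <- globalAlign("GATTACA", "GCATGCT", uniformScoringScheme())
#' r@score
#' @export
globalAlign <- function(s1, s2, scheme = defaultScoringScheme()) {
  n1 <- if (is(s1, "SequenceHandle")) s1@name else "s1"
  n2 <- if (is(s2, "SequenceHandle")) s2@name else "s2"
  a <- if (is(s1, "SequenceHandle")) s1@seq else toupper(s1)
  b <- if (is(s2, "SequenceHandle")) s2@seq else toupper(s2)
  d <- .gotoh(a, b, scheme, local = FALSE)
  n <- length(d$A); m <- length(d$B)
  fin <- c(M = d$M[n + 1, m + 1], Ix = d$Ix[n + 1, m + 1],
           Iy = d$Iy[n + 1, m + 1])
  state <- names(fin)[which.max(fin)]
  tb <- .traceback(d, n + 1L, m + 1L, state, local = FALSE)
  .alignResult(tb$a, tb$b, n1, n2, max(fin))
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Affine-gap local alignment: the match state is floored at zero and the
#' optimal sub-alignment ending at the best-scoring cell is emitted.  The
#' score is always >= 0; two sequences with no positive-scoring residue
#' pair yield score 0 and an empty alignment.  The start of the aligned
#' region in each input is reported through the emitted sequences'
#' offsets.
#'
#' @inheritParams globalAlign
#' @return a \linkS4class{PairwiseAlignmentResult}.
#' @export
localAlign <- function(s1, s2, scheme = defaultScoringScheme()) {
  n1 <- if (is(s1, "SequenceHandle")) s1@name else "s1"
  n2 <- if (is(s2, "SequenceHandle")) s2@name else "s2"
  a <- if (is(s1, "SequenceHandle")) s1@seq else toupper(s1)
  b <- if (is(s2, "SequenceHandle")) s2@seq else toupper(s2)
  d <- .gotoh(a, b, scheme, local = TRUE)
  best <- max(d$M)
  if (best <= 0) {
    aln <- new("AlignmentHandle",
               sequences = list(createSequence(n1, ""),
                                createSequence(n2, "")))
    return(new("PairwiseAlignmentResult", alignment = aln, score = 0,
               identity = NaN))
  }
  hit <- which(d$M == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  tb <- .traceback(d, hit[1], hit[2], "M", local = TRUE)
  .alignResult(tb$a, tb$b, n1, n2, best,
               offA = tb$i - 1L, offB = tb$j - 1L)
}

#' Percent sequence identity of a pairwise alignment
#'
#' 100 x (columns with equal, non-gap characters) / (columns where both
#' sequences are non-gap).  Columns containing a gap in either sequence
#' are excluded from the denominator.
#'
#' @param aln a two-sequence \linkS4class{AlignmentHandle}.
#' @return percentage in [0, 100].
#' @export
sequenceIdentity <- function(aln) {
  if (length(aln@sequences) != 2L)
    stop("sequence identity is defined for two-sequence alignments")
  a <- strsplit(aln@sequences[[1]]@seq, "")[[1]]
  b <- strsplit(aln@sequences[[2]]@seq, "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) stop("alignment has no aligned (gap-free) columns")
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Re-score an emitted pairwise alignment
#'
#' Sums substitution scores over aligned columns and affine gap costs
#' (\code{gapOpen + (L-1) * gapExtend} per gap run) over gap runs in
#' either sequence.  Used to verify that emitted alignments achieve the
#' reported dynamic-programming score.
#'
#' @param aln two-sequence \linkS4class{AlignmentHandle}.
#' @param scheme scoring scheme.
#' @return numeric score.
#' @export
scoreAlignment <- function(aln, scheme = defaultScoringScheme()) {
  a <- strsplit(aln@sequences[[1]]@seq, "")[[1]]
  b <- strsplit(aln@sequences[[2]]@seq, "")[[1]]
  stopifnot(length(a) == length(b))
  sc <- 0
  for (s in list(a, b)) {
    r <- rle(s == "-")
    sc <- sc + sum(ifelse(r$values, scheme$gapOpen +
                          (r$lengths - 1) * scheme$gapExtend, 0)[r$values])
  }
  both <- a != "-" & b != "-"
  if (any(both))
    sc <- sc + sum(scheme$matrix[cbind(a[both], b[both])])
  sc
}

# ---- column conservation ----------------------------------------------

.simCache <- new.env(parent = emptyenv())

# physico-chemical similarity proxy in [0,1]: per-pair normalised BLOSUM62,
# sim(a,b) = clip((B(a,b)-Bmin) / (min(B(a,a),B(b,b))-Bmin)); diagonal = 1
.similarityMatrix <- function() {
  if (!is.null(.simCache$m)) return(.simCache$m)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V","X")
  B <- .blosum62()[aa, aa]
  bmin <- min(B)
  d <- diag(B)
  denom <- outer(d, d, pmin) - bmin
  m <- (B - bmin) / denom
  m[m < 0] <- 0; m[m > 1] <- 1
  diag(m) <- 1
  .simCache$m <- m
  m
}

#' Per-column conservation of an alignment
#'
#' For every alignment column, the mean over unordered sequence pairs of
#' a residue similarity: with \code{normalized = TRUE} (default) the
#' similarity is a physico-chemical proxy scaled to [0, 1] (per-pair
#' normalised BLOSUM62; identical residues score exactly 1), and pairs
#' involving a gap contribute 0 -- so a column is 1 exactly when all
#' residues are identical and gap-free, and 0 when all-gap.  With
#' \code{normalized = FALSE} the raw substitution scores are averaged and
#' gap pairs contribute the matrix minimum.  The score is invariant under
#' permutation of the sequences.
#'
#' @param aln an \linkS4class{AlignmentHandle} of at least two sequences.
#' @param normalized scale to [0, 1] as described.
#' @param similarity optional replacement similarity matrix (row/column
#'   names = residue letters).
#' @return numeric vector, one score per column.
#' @export
conservation <- function(aln, normalized = TRUE, similarity = NULL) {
  ns <- length(aln@sequences)
  if (ns < 2L) stop("conservation needs an alignment of >= 2 sequences")
  sim <- if (!is.null(similarity)) similarity
         else if (normalized) .similarityMatrix() else .blosum62()
  gapVal <- if (normalized) 0 else min(sim)
  chars <- vapply(aln@sequences, function(s)
    strsplit(s@seq, "")[[1]], character(alignmentLength(aln)))
  chars <- matrix(chars, ncol = ns)  # columns = sequences
  pairs <- utils::combn(ns, 2)
  apply(chars, 1, function(col) {
    vals <- apply(pairs, 2, function(p) {
      a <- col[p[1]]; b <- col[p[2]]
      if (a == "-" || b == "-") gapVal
      else {
        if (!a %in% rownames(sim)) a <- "X"
        if (!b %in% rownames(sim)) b <- "X"
        sim[a, b]
      }
    })
    mean(vals)
  })
}
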