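# Least-squares rigid superposition (Kabsch via SVD) and alignment-guided
# annotation transfer.

#' Superpose two equally sized atom sets
#'
#' Computes the proper rotation and translation that minimise the RMSD
#' between the atoms of \code{mobile} and \code{reference}
#' (Kabsch algorithm: SVD of the covariance matrix, with the sign of the
#' smallest singular vector flipped when the determinant would be -1, so
#' the result is always a rotation, never a reflection).
#' Correspondence is positional: the i-th atom of \code{mobile} is paired
#' with the i-th atom of \code{reference} in view iteration order -- there
#' is no name-based matching, so the two views must list equivalent atoms
#' in the same order.  Any equally sized views work: CA traces, ligand
#' atoms, binding-site side chains.
#'
#' @param mobile,reference \linkS4class{EntityView}s (or handles) with
#'   equal atom counts >= 3.
#' @param apply transform the mobile handle's coordinates in place (every
#'   view of that handle sees the move).
#' @return a \linkS4class{SuperpositionResult}.
#' @examples
#' a <- makePolyalaHelix(6)
#' b <- makePolyalaHelix(6)
#' applyTransform(b, diag(3), c(5, 0, 0))
#' superpose(asView(b), asView(a))@rmsd   # ~0
#' @export
superpose <- function(mobile, reference, apply = FALSE) {
  P <- positions(mobile)   # mobile
  Q <- positions(reference)
  if (nrow(P) != nrow(Q))
    stop("atom count mismatch: mobile has ", nrow(P), ", reference has ",
         nrow(Q))
  if (nrow(P) < 3L) stop("superposition needs at least 3 atom pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))          # 3x3 covariance
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  if (min(s$d) < 1e-8 * max(s$d, 1e-300))
    warning("degenerate (collinear or planar-thin) atom set; ",
            "superposition may be ill-conditioned")
  t <- as.numeric(cq - R %*% cp)
  moved <- sweep(P %*% t(R), 2, -t)
  r <- sqrt(mean(rowSums((moved - Q)^2)))
  if (apply) applyTransform(mobile, R, t)
  new("SuperpositionResult", rotation = R, translation = t, rmsd = r,
      atomCount = nrow(P))
}

#' Root-mean-square deviation between two atom sets
#'
#' Pairs atoms positionally (i-th with i-th) and returns
#' \code{sqrt(mean(|a_i - b_i|^2))}, optionally after applying a rigid
#' transform to the first set.  No superposition is performed; combine
#' with \code{\link{superpose}} for the minimised value.
#'
#' @param a,b views or handles with equal atom counts.
#' @param rotation,translation optional transform applied to \code{a}.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, rotation = NULL, translation = c(0, 0, 0)) {
  P <- positions(a); Q <- positions(b)
  if (nrow(P) != nrow(Q)) stop("atom count mismatch")
  if (!nrow(P)) stop("empty atom sets")
  if (!is.null(rotation)) P <- sweep(P %*% t(rotation), 2, -translation)
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Transfer residue annotations through a sequence alignment
#'
#' Annotates residues of a target structure from an annotated source
#' structure related by a pairwise sequence alignment: every source
#' residue matched by \code{selection} (a query string evaluated on the
#' source's attached view, e.g. a \code{within} query picking
#' ligand-contacting residues) is mapped through the alignment -- source
#' residue index to alignment column, column to target residue index --
#' and the aligned target residue, when the column is not a gap in the
#' target, receives the boolean generic property \code{propKey = TRUE}
#' (queryable as \code{gr:propKey}).  Source residues facing a gap are
#' skipped.
#'
#' @param srcSeq,dstSeq \linkS4class{SequenceHandle}s with attached views
#'   (see \code{\link{attachView}}); both must be rows of \code{aln}.
#' @param aln an \linkS4class{AlignmentHandle} containing both sequences.
#' @param selection query string selecting source atoms; their residues
#'   are the annotation source.
#' @param propKey generic-property key set on target residues.
#' @return number of target residues annotated.
#' @export
transferAnnotation <- function(srcSeq, dstSeq, aln, selection,
                               propKey = "transferred") {
  nmatch <- function(s) which(vapply(aln@sequences, function(q)
    identical(q@seq, s@seq) && identical(q@name, s@name), logical(1)))
  if (!length(nmatch(srcSeq)) || !length(nmatch(dstSeq)))
    stop("both sequences must be members of the alignment")
  srcView <- attachedView(srcSeq); dstView <- attachedView(dstSeq)
  if (is.null(srcView) || is.null(dstView))
    stop("both sequences must have attached structure views")
  sel <- select(srcView, selection)
  selRes <- unique(atoms(sel)$resId)
  srcRes <- residues(srcView)
  dstRes <- residues(dstView)
  dstHandle <- dstView@handle
  count <- 0L
  for (rid in selRes) {
    k <- match(rid, srcRes$resId)           # k-th residue of the source view
    pos <- residueIndexToPos(srcSeq, srcSeq@offset + k)
    dstIdx <- posToResidueIndex(dstSeq, pos)
    if (is.na(dstIdx)) next                 # gap opposite this residue
    dr <- dstRes[dstIdx - dstSeq@offset, ]
    setProp(dstHandle, propKey, TRUE, level = "residue", id = dr$resId)
    count <- count + 1L
  }
  count
}
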