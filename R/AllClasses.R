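#' @import methods
#' @importFrom stats fft rnorm runif sd
#' @importFrom utils head tail
NULL

#' EntityHandle: a molecular structure
#'
#' An \code{EntityHandle} owns the full chain/residue/atom/bond tree of a
#' molecular structure (a protein, nucleic acid, ligand set or any other
#' molecule).  The handle has reference semantics: its state lives in an
#' environment, so coordinate edits, bond building and generic-property
#' assignment are visible through every \linkS4class{EntityView} derived
#' from it.
#'
#' Atoms, residues and chains are stored as flat tables keyed by stable
#' integer ids; use \code{\link{atoms}}, \code{\link{residues}},
#' \code{\link{chainNames}}, \code{\link{positions}} and
#' \code{\link{bonds}} to inspect them.
#'
#' @slot ptr environment holding the mutable structure state.
#' @seealso \code{\link{createEntity}}, \code{\link{select}},
#'   \code{\link{createView}}
#' @export
setClass("EntityHandle", representation(ptr = "environment"))

#' EntityView: a live subset of an EntityHandle
#'
#' A view references a subset of the atoms of its handle (plus their parent
#' residues and chains, and every bond whose two endpoints are both in the
#' subset).  It copies nothing: positions and generic properties read
#' through a view always reflect the handle's current state.  Deleting
#' atoms from the handle invalidates existing views (tracked with a
#' generation counter; stale views raise an error on access).
#'
#' @slot handle the parent \linkS4class{EntityHandle}.
#' @slot atomIds integer atom ids included in the view, in view order.
#' @slot generation handle generation this view was created at.
#' @seealso \code{\link{select}}, \code{\link{createView}}
#' @export
setClass("EntityView",
  representation(handle = "EntityHandle", atomIds = "integer",
                 generation = "integer"))

#' IOProfile: import behaviour flags
#'
#' Aggregates the flags that fine-tune structure import: strictness
#' (abort on a nonconforming record vs skip it), which connectivity
#' processor to run after import, and whether HETATM records are read.
#'
#' @slot strict abort on malformed records (when not fault tolerant,
#'   unknown residues/atoms also become errors during connectivity).
#' @slot processConnectivity one of \code{"rule_based"},
#'   \code{"heuristic"}, \code{"none"}.
#' @slot faultTolerant skip bad records with a warning instead of aborting.
#' @slot readHetatms import HETATM records.
#' @seealso \code{\link{ioProfile}}, \code{\link{readPDB}}
#' @export
setClass("IOProfile",
  representation(strict = "logical", processConnectivity = "character",
                 faultTolerant = "logical", readHetatms = "logical"))

#' Trajectory: coordinate frames over a topology
#'
#' Frames of a CHARMM DCD trajectory tied to the \linkS4class{EntityHandle}
#' describing the topology.  In \code{in_memory} mode all (strided) frames
#' are resident; in \code{lazy} mode only the header is parsed and frames
#' are fetched from disk on demand through an LRU cache.  Both modes return
#' bit-identical coordinates.
#'
#' @slot ptr environment with frame storage / cache state.
#' @seealso \code{\link{readDCD}}, \code{\link{framePositions}},
#'   \code{\link{applyFrame}}
#' @export
setClass("Trajectory", representation(ptr = "environment"))

#' SequenceHandle: a single, possibly gapped sequence
#'
#' Holds a one-letter-code sequence in which \code{"-"} marks alignment
#' gaps.  The handle maintains a run-length gap list so that mapping
#' between alignment positions and residue indices costs time proportional
#' to the number of gaps, not the position.  A structure
#' (\linkS4class{EntityView}) whose residues match the sequence may be
#' attached, linking sequence positions to residues.
#'
#' @slot name sequence name.
#' @slot seq the sequence string (uppercase, \code{"-"} gaps).
#' @slot offset number of residues of the full molecule preceding the
#'   first residue in this (sub)sequence; residue index of the first
#'   non-gap character is \code{offset + 1}.
#' @slot gapList two-column integer matrix \code{(start, length)} of gap
#'   runs, 1-based start positions, ascending.
#' @slot attached list of length 0 or 1 holding an attached
#'   \linkS4class{EntityView}.
#' @seealso \code{\link{createSequence}}, \code{\link{posToResidueIndex}},
#'   \code{\link{attachView}}
#' @export
setClass("SequenceHandle",
  representation(name = "character", seq = "character", offset = "integer",
                 gapList = "matrix", attached = "list"))

#' AlignmentHandle: sequences related by an alignment
#'
#' A list of \linkS4class{SequenceHandle}s of equal string length.  The
#' interface is column-oriented: columns may be inspected, inserted and
#' removed, and per-column conservation can be computed with
#' \code{\link{conservation}}.
#'
#' @slot sequences list of \linkS4class{SequenceHandle}, equal lengths.
#' @seealso \code{\link{createAlignment}}, \code{\link{insertGapColumn}}
#' @export
setClass("AlignmentHandle", representation(sequences = "list"))

#' SequenceList: an ordered list of sequences
#'
#' Unlike an \linkS4class{AlignmentHandle} the sequences need not have the
#' same length; suited e.g. for database-search results.
#'
#' @slot sequences list of \linkS4class{SequenceHandle}.
#' @export
setClass("SequenceList", representation(sequences = "list"))

#' CompoundLib: residue topology dictionary
#'
#' Maps 3-letter residue codes to their atom names/elements, intra-residue
#' bond list, one-letter code and chemical class (amino acid, nucleotide,
#' ligand or water).  Used by the rule-based connectivity processor.
#'
#' @slot entries named list of compound entries.
#' @seealso \code{\link{loadCompoundLibrary}}, \code{\link{ruleBasedProcess}}
#' @export
setClass("CompoundLib", representation(entries = "list"))

#' ImageHandle: a domain-aware 1/2/3-D image
#'
#' A scalar pixel/voxel buffer together with its sampling (Angstrom per
#' pixel, per dimension), spatial origin and the currently active domain
#' (\code{"spatial"} or \code{"frequency"}).  Applying \code{\link{fftImage}}
#' toggles the domain; the handle remembers whether a frequency-domain
#' buffer came from a real spatial image (conjugate symmetry), so that the
#' back transform returns a real image.
#'
#' @slot data numeric or complex array (1, 2 or 3 dimensions).
#' @slot sampling Angstrom per pixel for each dimension.
#' @slot origin spatial position (Angstrom) of the first voxel centre.
#' @slot domain \code{"spatial"} or \code{"frequency"}.
#' @slot conjugateSymmetric frequency-domain flag: buffer is the transform
#'   of a real spatial image.
#' @seealso \code{\link{imageHandle}}, \code{\link{fftImage}},
#'   \code{\link{entityToDensity}}
#' @export
setClass("ImageHandle",
  representation(data = "array", sampling = "numeric", origin = "numeric",
                 domain = "character", conjugateSymmetric = "logical"))

#' SuperpositionResult: rigid-body superposition output
#'
#' @slot rotation 3x3 proper rotation matrix (determinant +1).
#' @slot translation length-3 translation vector (Angstrom).
#' @slot rmsd root-mean-square deviation (Angstrom) after superposition.
#' @slot atomCount number of atom pairs used.
#' @seealso \code{\link{superpose}}
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", atomCount = "integer"))

#' PairwiseAlignmentResult: output of the dynamic-programming aligners
#'
#' @slot alignment \linkS4class{AlignmentHandle} with the two aligned
#'   sequences (offsets record the start of the aligned region for local
#'   alignments).
#' @slot score alignment score under the scoring scheme used.
#' @slot identity percent sequence identity over aligned (both non-gap)
#'   columns.
#' @seealso \code{\link{globalAlign}}, \code{\link{localAlign}}
#' @export
setClass("PairwiseAlignmentResult",
  representation(alignment = "AlignmentHandle", score = "numeric",
                 identity = "numeric"))

setValidity("EntityView", function(object) {
  e <- object@handle@ptr
  if (!is.integer(object@atomIds)) return("atomIds must be integer")
  if (anyDuplicated(object@atomIds)) return("duplicate atom ids in view")
  if (length(object@atomIds) && !all(object@atomIds %in% e$atoms$id))
    return("view references atoms not in its handle")
  TRUE
})

setValidity("IOProfile", function(object) {
  if (!object@processConnectivity %in% c("rule_based", "heuristic", "none"))
    return("processConnectivity must be rule_based, heuristic or none")
  TRUE
})

setValidity("AlignmentHandle", function(object) {
  if (length(object@sequences) < 1L) return("alignment needs >= 1 sequence")
  if (!all(vapply(object@sequences, is, logical(1), "SequenceHandle")))
    return("sequences must be SequenceHandle objects")
  n <- vapply(object@sequences, function(s) nchar(s@seq), integer(1))
  if (length(unique(n)) > 1L) return("sequences must have equal length")
  TRUE
})

setValidity("ImageHandle", function(object) {
  d <- length(dim(object@data))
  if (d < 1L || d > 3L) return("image must be 1, 2 or 3 dimensional")
  if (length(object@sampling) != d) return("sampling length != rank")
  if (any(object@sampling <= 0)) return("sampling must be positive")
  if (!object@domain %in% c("spatial", "frequency"))
    return("domain must be spatial or frequency")
  TRUE
})

setMethod("show", "EntityHandle", function(object) {
  e <- object@ptr
  cat(sprintf("EntityHandle '%s': %d chain(s), %d residue(s), %d atom(s), %d bond(s)\n",
      e$name, nrow(e$chains), nrow(e$residues), nrow(e$atoms), nrow(e$bonds)))
})

setMethod("show", "EntityView", function(object) {
  .checkGeneration(object)
  a <- atoms(object)
  cat(sprintf("EntityView: %d chain(s), %d residue(s), %d atom(s), %d bond(s)\n",
      length(unique(a$chainId)), length(unique(a$resId)), nrow(a),
      nrow(bonds(object))))
})

setMethod("show", "SequenceHandle", function(object) {
  cat(sprintf("SequenceHandle '%s' (offset %d%s)\n  %s\n", object@name,
      object@offset, if (length(object@attached)) ", attached" else "",
      object@seq))
})

setMethod("show", "AlignmentHandle", function(object) {
  cat(sprintf("AlignmentHandle: %d sequence(s), %d column(s)\n",
      length(object@sequences),
      if (length(object@sequences)) nchar(object@sequences[[1]]@seq) else 0L))
  for (s in object@sequences) cat(sprintf("  %-12s %s\n", s@name, s@seq))
})

setMethod("show", "ImageHandle", function(object) {
  cat(sprintf("ImageHandle: %s, %s domain%s, sampling %s A/px\n",
      paste(dim(object@data), collapse = "x"), object@domain,
      if (object@domain == "frequency" && object@conjugateSymmetric)
        " (conjugate symmetric)" else "",
      paste(signif(object@sampling, 4), collapse = "x")))
})

setMethod("show", "Trajectory", function(object) {
  p <- object@ptr
  cat(sprintf("Trajectory: %d frame(s) x %d atom(s), %s mode, stride %d\n",
      p$frameCount, p$natom, p$mode, p$stride))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: %d atoms, rmsd %.4f A\n",
      object@atomCount, object@rmsd))
})

setMethod("show", "PairwiseAlignmentResult", function(object) {
  cat(sprintf("PairwiseAlignmentResult: score %g, identity %.1f%%\n",
      object@score, object@identity))
  show(object@alignment)
})

setMethod("show", "CompoundLib", function(object) {
  cat(sprintf("CompoundLib: %d compound(s)\n", length(object@entries)))
})
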