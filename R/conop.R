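#' Load a compound library
#'
#' Reads a residue-topology dictionary from the documented JSON format:
#' an object mapping 3-letter residue codes to
#' \code{{one_letter, class, atoms: {name: element, ...}, bonds: [[a,b], ...]}},
#' with \code{class} one of \code{amino_acid}, \code{nucleotide},
#' \code{ligand}, \code{water}.  The library bundled with the package
#' (\code{defaultCompoundLibrary()}) covers the 20 standard amino acids,
#' the 8 standard (deoxy)ribonucleotides, water (HOH) and haem (HEM),
#' with heavy-atom topologies derived from standard PDB chemical
#' component definitions.
#'
#' @param path path to a JSON compound dictionary.
#' @return a \linkS4class{CompoundLib}.
#' @export
loadCompoundLibrary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("malformed compound library: not a JSON object")
  entries <- lapply(names(raw), function(code) {
    e <- raw[[code]]
    if (is.null(e$atoms) || is.null(e$bonds) || is.null(e$class) ||
        is.null(e$one_letter))
      stop("malformed compound library entry: ", code)
    atomNames <- names(e$atoms)
    elements <- vapply(e$atoms, as.character, character(1))
    bonds <- lapply(e$bonds, function(b) {
      b <- as.character(unlist(b))
      if (length(b) != 2L)
        stop("malformed bond in compound ", code)
      if (!all(b %in% atomNames))
        stop("compound ", code, " bond references undeclared atom: ",
             paste(setdiff(b, atomNames), collapse = ", "))
      b
    })
    if (!e$class %in% c("amino_acid", "nucleotide", "ligand", "water"))
      stop("compound ", code, " has unknown class ", e$class)
    list(code = code, oneLetter = as.character(e$one_letter),
         class = as.character(e$class), atoms = atomNames,
         elements = stats::setNames(elements, atomNames), bonds = bonds)
  })
  names(entries) <- names(raw)
  new("CompoundLib", entries = entries)
}

.complibCache <- new.env(parent = emptyenv())

#' @rdname loadCompoundLibrary
#' @export
defaultCompoundLibrary <- function() {
  if (is.null(.complibCache$lib)) {
    path <- system.file("extdata", "compound_library.json", package = "molkit",
                        mustWork = TRUE)
    .complibCache$lib <- loadCompoundLibrary(path)
  }
  .complibCache$lib
}

#' Look up one compound
#' @param lib a \linkS4class{CompoundLib}.
#' @param code 3-letter residue code.
#' @return the entry (list) or \code{NULL}.
#' @export
compoundEntry <- function(lib, code) lib@entries[[code]]

# covalent radii (Angstrom) used by the heuristic builder
.covRadii <- c(H = 0.31, C = 0.77, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
               FE = 1.32)
.covDefault <- 1.5
.covTolerance <- 0.4
.interResidueCutoff <- 2.5

.covRadius <- function(element) {
  r <- .covRadii[toupper(element)]
  ifelse(is.na(r), .covDefault, r)
}

.addBonds <- function(e, a, b, order = 1L) {
  if (!length(a)) return(invisible())
  new <- data.frame(a = pmin(a, b), b = pmax(a, b), order = as.integer(order))
  all <- rbind(e$bonds, new)
  all <- all[!duplicated(all[, c("a", "b")]), , drop = FALSE]
  rownames(all) <- NULL
  e$bonds <- all
  invisible()
}

#' Rule-based connectivity and topology processing
#'
#' Connects the atoms of an entity according to a compound library:
#' intra-residue bonds are the library's bond list for the residue code,
#' restricted to the atoms actually present; consecutive residues in a
#' chain are linked by a peptide bond C(i)-N(i+1) (amino acids) or a
#' phosphodiester bond O3'(i)-P(i+1) (nucleotides) when the inter-atom
#' distance is at most 2.5 Angstrom.  One-letter codes and chemical
#' classes are assigned from the library.  Residues missing from the
#' library and atom names unknown to their compound are reported as
#' diagnostics; with \code{strict = TRUE} the first such finding raises an
#' error instead, which is the recommended setting for automated pipelines.
#' The operation is idempotent: re-running adds no bonds and repeats the
#' same diagnostics.
#'
#' @param entity an \linkS4class{EntityHandle} (mutated in place).
#' @param lib a \linkS4class{CompoundLib}; default the bundled library.
#' @param strict raise an error on the first unknown residue/atom.
#' @return a data.frame of diagnostics with columns \code{severity},
#'   \code{chain}, \code{resnum}, \code{resname}, \code{kind}
#'   (\code{unknown_residue}, \code{unknown_atom}, \code{missing_atom})
#'   and \code{message}, invisibly when empty.
#' @export
ruleBasedProcess <- function(entity, lib = defaultCompoundLibrary(),
                             strict = FALSE) {
  e <- .handleOf(entity)@ptr
  diag <- list()
  note <- function(severity, res, kind, msg) {
    rec <- data.frame(severity = severity, chain = res$chain,
                      resnum = res$resnum, resname = res$resname,
                      kind = kind, message = msg, stringsAsFactors = FALSE)
    if (strict && kind %in% c("unknown_residue", "unknown_atom"))
      stop("connectivity error (strict): ", msg)
    diag[[length(diag) + 1L]] <<- rec
  }
  res <- e$residues
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    entry <- lib@entries[[r$resname]]
    sel <- e$atoms$resId == r$resId
    anames <- e$atoms$name[sel]
    aids <- e$atoms$id[sel]
    if (is.null(entry)) {
      note("warning", r, "unknown_residue",
           paste0("residue ", r$resname, " ", r$chain, ".", r$resnum,
                  " not in compound library"))
      next
    }
    e$residues$olc[i] <- entry$oneLetter
    e$residues$chemClass[i] <- entry$class
    e$residues$isProtein[i] <- entry$class == "amino_acid"
    unknown <- setdiff(anames, entry$atoms)
    for (u in unknown)
      note("warning", r, "unknown_atom",
           paste0("atom ", u, " unknown in compound ", r$resname))
    missing <- setdiff(setdiff(entry$atoms, "OXT"), anames)
    for (m in missing)
      note("warning", r, "missing_atom",
           paste0("atom ", m, " of compound ", r$resname, " absent"))
    idx <- stats::setNames(aids, anames)
    for (b in entry$bonds) {
      if (all(b %in% anames)) .addBonds(e, idx[[b[1]]], idx[[b[2]]])
    }
  }
  # inter-residue links between consecutive residues of a chain
  for (ci in unique(res$chainId)) {
    rr <- res[res$chainId == ci, , drop = FALSE]
    if (nrow(rr) < 2L) next
    cls <- e$residues$chemClass[match(rr$resId, e$residues$resId)]
    for (k in seq_len(nrow(rr) - 1L)) {
      pair <- if (cls[k] == "amino_acid" && cls[k + 1L] == "amino_acid")
        c("C", "N")
      else if (cls[k] == "nucleotide" && cls[k + 1L] == "nucleotide")
        c("O3'", "P")
      else next
      ai <- e$atoms$id[e$atoms$resId == rr$resId[k] & e$atoms$name == pair[1]]
      bi <- e$atoms$id[e$atoms$resId == rr$resId[k + 1L] &
                       e$atoms$name == pair[2]]
      if (length(ai) == 1L && length(bi) == 1L) {
        d <- sqrt(sum((e$pos[match(ai, e$atoms$id), ] -
                       e$pos[match(bi, e$atoms$id), ])^2))
        if (d <= .interResidueCutoff) .addBonds(e, ai, bi)
      }
    }
  }
  out <- if (length(diag)) do.call(rbind, diag) else
    data.frame(severity = character(), chain = character(),
               resnum = integer(), resname = character(), kind = character(),
               message = character(), stringsAsFactors = FALSE)
  if (nrow(out)) out else invisible(out)
}

#' Heuristic distance-based connectivity
#'
#' A quick-and-dirty connectivity builder for interactive use and for
#' structures with loose naming conventions (e.g. from simulations).
#' Residues whose code is known to the lookup library are bonded by
#' topology exactly as in \code{\link{ruleBasedProcess}}; for unknown
#' residues atoms \code{a}, \code{b} are bonded when
#' \code{|pos(a)-pos(b)| <= r_cov(a) + r_cov(b) + 0.4} Angstrom
#' (covalent radii: H 0.31, C 0.77, N 0.71, O 0.66, S 1.05, P 1.07,
#' Fe 1.32, otherwise 1.5), with hydrogens limited to a single bond to
#' their nearest heavy atom.  Never fails: unknown anything is simply
#' left to the distance rule.
#'
#' @param entity an \linkS4class{EntityHandle} (mutated in place).
#' @param lib lookup library for standard residues.
#' @return the entity, invisibly.
#' @export
heuristicProcess <- function(entity, lib = defaultCompoundLibrary()) {
  e <- .handleOf(entity)@ptr
  res <- e$residues
  unknownIds <- integer()
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    entry <- lib@entries[[r$resname]]
    sel <- e$atoms$resId == r$resId
    if (is.null(entry)) {
      unknownIds <- c(unknownIds, e$atoms$id[sel])
      next
    }
    e$residues$olc[i] <- entry$oneLetter
    e$residues$chemClass[i] <- entry$class
    e$residues$isProtein[i] <- entry$class == "amino_acid"
    anames <- e$atoms$name[sel]
    idx <- stats::setNames(e$atoms$id[sel], anames)
    for (b in entry$bonds)
      if (all(b %in% anames)) .addBonds(e, idx[[b[1]]], idx[[b[2]]])
    extra <- e$atoms$id[sel][!anames %in% entry$atoms]
    unknownIds <- c(unknownIds, extra)
  }
  # inter-residue links for known polymer residues
  for (ci in unique(res$chainId)) {
    rr <- e$residues[e$residues$chainId == ci, , drop = FALSE]
    if (nrow(rr) < 2L) next
    for (k in seq_len(nrow(rr) - 1L)) {
      pair <- if (rr$chemClass[k] == "amino_acid" &&
                  rr$chemClass[k + 1L] == "amino_acid") c("C", "N")
      else if (rr$chemClass[k] == "nucleotide" &&
               rr$chemClass[k + 1L] == "nucleotide") c("O3'", "P")
      else next
      ai <- e$atoms$id[e$atoms$resId == rr$resId[k] & e$atoms$name == pair[1]]
      bi <- e$atoms$id[e$atoms$resId == rr$resId[k + 1L] &
                       e$atoms$name == pair[2]]
      if (length(ai) == 1L && length(bi) == 1L) {
        d <- sqrt(sum((e$pos[match(ai, e$atoms$id), ] -
                       e$pos[match(bi, e$atoms$id), ])^2))
        if (d <= .interResidueCutoff) .addBonds(e, ai, bi)
      }
    }
  }
  # distance rule over atoms not covered by the lookup tables
  if (length(unknownIds)) .distanceConnect(e, unique(unknownIds))
  invisible(.handleOf(entity))
}

.distanceConnect <- function(e, ids) {
  rows <- match(ids, e$atoms$id)
  elem <- toupper(e$atoms$element[rows])
  isH <- elem == "H"
  rad <- .covRadius(elem)
  pos <- e$pos[rows, , drop = FALSE]
  n <- length(ids)
  if (n < 2L) return(invisible())
  pairsA <- integer(); pairsB <- integer()
  hPartner <- rep(NA_integer_, n); hDist <- rep(Inf, n)
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(pos[(i + 1L):n, , drop = FALSE]) - pos[i, ])^2))
    cut <- rad[i] + rad[(i + 1L):n] + .covTolerance
    hit <- which(d <= cut)
    for (hidx in hit) {
      j <- i + hidx
      if (isH[i] && isH[j]) next  # never bond H to H
      if (isH[i]) {
        if (d[hidx] < hDist[i]) { hDist[i] <- d[hidx]; hPartner[i] <- j }
      } else if (isH[j]) {
        if (d[hidx] < hDist[j]) { hDist[j] <- d[hidx]; hPartner[j] <- i }
      } else {
        pairsA <- c(pairsA, ids[i]); pairsB <- c(pairsB, ids[j])
      }
    }
  }
  hs <- which(!is.na(hPartner))
  if (length(hs)) {
    pairsA <- c(pairsA, ids[hs]); pairsB <- c(pairsB, ids[hPartner[hs]])
  }
  if (length(pairsA)) .addBonds(e, pairsA, pairsB)
  invisible()
}
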