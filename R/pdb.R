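#' Construct an IO profile
#'
#' @param strict abort on the first malformed ATOM/HETATM record (unless
#'   \code{faultTolerant}); non-strict parsing tolerates missing optional
#'   columns.
#' @param processConnectivity connectivity processor run after import:
#'   \code{"rule_based"}, \code{"heuristic"} or \code{"none"}.
#' @param faultTolerant skip malformed records with a warning instead of
#'   aborting.
#' @param readHetatms import HETATM records.
#' @return an \linkS4class{IOProfile}.
#' @details The default profile is strict, with rule-based connectivity
#'   and HETATM import -- imports abort on nonconforming files, the
#'   recommended behaviour for automated pipelines.  Connectivity
#'   diagnostics (unknown residues/atoms) are always reported, never
#'   fatal, during import; use \code{\link{ruleBasedProcess}} directly
#'   for strict connectivity checking.
#' @export
ioProfile <- function(strict = TRUE, processConnectivity = "rule_based",
                      faultTolerant = FALSE, readHetatms = TRUE) {
  new("IOProfile", strict = strict,
      processConnectivity = processConnectivity,
      faultTolerant = faultTolerant, readHetatms = readHetatms)
}

.num <- function(s) suppressWarnings(as.numeric(s))

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records at their PDB v3.3 fixed columns (serial,
#' name, altloc, resname, chain, resseq, icode, x, y, z, occupancy,
#' B factor, element, charge).  Only the first MODEL of multi-model files
#' is read.  Alternate locations are resolved to the conformer with the
#' highest occupancy (ties: lowest altloc letter).  With a strict,
#' non-fault-tolerant profile any malformed record aborts the import with
#' its line number; a fault-tolerant profile skips the record and logs a
#' warning instead.  After parsing, connectivity is derived according to
#' the profile.  Import diagnostics (skipped records, unknown residues)
#' are retrievable with \code{ioDiagnostics}.
#'
#' @param path PDB file.
#' @param profile an \linkS4class{IOProfile}.
#' @return an \linkS4class{EntityHandle}.
#' @export
readPDB <- function(path, profile = ioProfile()) {
  lines <- readLines(path, warn = FALSE)
  rows <- list(); notes <- list()
  note <- function(line, msg) notes[[length(notes) + 1L]] <<-
    sprintf("line %d: %s", line, msg)
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    rec <- substr(l, 1, 6)
    if (rec == "ENDMDL") break  # first model only
    if (rec != "ATOM  " && rec != "HETATM") next
    het <- rec == "HETATM"
    if (het && !profile@readHetatms) next
    f <- list(
      serial = trimws(substr(l, 7, 11)), name = trimws(substr(l, 13, 16)),
      altloc = substr(l, 17, 17), resname = trimws(substr(l, 18, 20)),
      chain = substr(l, 22, 22), resseq = trimws(substr(l, 23, 26)),
      icode = trimws(substr(l, 27, 27)),
      x = .num(substr(l, 31, 38)), y = .num(substr(l, 39, 46)),
      z = .num(substr(l, 47, 54)),
      occ = .num(substr(l, 55, 60)), bfac = .num(substr(l, 61, 66)),
      element = trimws(substr(l, 77, 78)),
      chargeStr = trimws(substr(l, 79, 80)))
    bad <- is.na(f$x) || is.na(f$y) || is.na(f$z) || !nzchar(f$name) ||
      !nzchar(f$resname) || is.na(suppressWarnings(as.integer(f$resseq)))
    if (profile@strict && !bad) {
      bad <- is.na(f$occ) || is.na(f$bfac)
    }
    if (bad) {
      if (profile@faultTolerant) {
        note(ln, paste0("skipping malformed ", trimws(rec), " record"))
        next
      }
      stop(sprintf("PDB import error at line %d of %s: malformed %s record",
                   ln, path, trimws(rec)))
    }
    charge <- 0
    if (nzchar(f$chargeStr)) {
      m <- regmatches(f$chargeStr, regexec("^([0-9])([+-])$", f$chargeStr))[[1]]
      if (length(m) == 3L)
        charge <- as.numeric(m[2]) * if (m[3] == "-") -1 else 1
    }
    element <- f$element
    if (!nzchar(element))
      element <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1", f$name))
    rows[[length(rows) + 1L]] <- data.frame(chain = f$chain,
      resname = f$resname, resnum = as.integer(f$resseq), icode = f$icode,
      name = f$name, altloc = f$altloc, element = element,
      x = f$x, y = f$y, z = f$z,
      occ = if (is.na(f$occ)) 1 else f$occ,
      bfac = if (is.na(f$bfac)) 0 else f$bfac,
      charge = charge, ishetatm = het, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(df)) {
    # alt-loc resolution: keep highest occupancy, ties to lowest letter
    key <- paste(df$chain, df$resnum, df$icode, df$name, sep = "\r")
    keep <- rep(TRUE, nrow(df))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[order(-df$occ[idx], df$altloc[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
    df <- df[keep, , drop = FALSE]
    df$altloc <- NULL
  }
  ent <- if (is.null(df)) createEntity(data.frame(chain = character(),
      resname = character(), resnum = integer(), name = character(),
      element = character(), x = numeric(), y = numeric(), z = numeric()))
    else createEntity(df, name = basename(path))
  if (atomCount(ent) > 0L) {
    if (profile@processConnectivity == "rule_based") {
      d <- ruleBasedProcess(ent, strict = FALSE)
      if (nrow(d)) notes <- c(notes, as.list(d$message))
    } else if (profile@processConnectivity == "heuristic") {
      heuristicProcess(ent)
    }
  }
  ent@ptr$ioDiagnostics <- unlist(notes, use.names = FALSE)
  ent
}

#' @rdname readPDB
#' @param entity an entity returned by \code{readPDB}.
#' @export
ioDiagnostics <- function(entity) {
  d <- .handleOf(entity)@ptr$ioDiagnostics
  if (is.null(d)) character() else d
}

#' Write a PDB coordinate file
#'
#' Writes the atoms of a handle or view as fixed-column ATOM/HETATM
#' records (TER between chains, END at the end).  A view writes exactly
#' its own atoms.  Reading the file back with a strict profile reproduces
#' chains, residues, atom names and positions to 3 decimals.
#'
#' @param x handle or view.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePDB <- function(x, path) {
  a <- atoms(x); p <- positions(x)
  lines <- character(); serial <- 0L
  lastChain <- NULL
  for (i in seq_len(nrow(a))) {
    if (!is.null(lastChain) && a$chain[i] != lastChain) {
      lines <- c(lines, "TER")
    }
    lastChain <- a$chain[i]
    serial <- serial + 1L
    if (nchar(a$resname[i]) > 3L)
      stop("residue name '", a$resname[i], "' exceeds the 3-character field")
    if (nchar(a$name[i]) > 4L)
      stop("atom name '", a$name[i], "' exceeds the 4-character field")
    if (nchar(a$chain[i]) > 1L)
      stop("chain name '", a$chain[i], "' exceeds the 1-character field")
    xyz <- sprintf("%8.3f", p[i, ])
    if (any(nchar(xyz) > 8L))
      stop("coordinate overflow: |value| too large for the 8.3 field")
    nm <- a$name[i]
    nmf <- if (nchar(nm) >= 4L) nm else sprintf("%-4s", paste0(" ", nm))
    chg <- if (a$charge[i] == 0) "  " else
      sprintf("%d%s", abs(a$charge[i]), if (a$charge[i] < 0) "-" else "+")
    lines <- c(lines, sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d%1s   %s%s%s%6.2f%6.2f          %2s%2s",
      if (a$ishetatm[i]) "HETATM" else "ATOM", serial, nmf, " ",
      a$resname[i], a$chain[i], a$resnum[i],
      if (nzchar(a$icode[i])) a$icode[i] else " ",
      xyz[1], xyz[2], xyz[3], a$occ[i], a$bfac[i],
      toupper(a$element[i]), chg))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
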