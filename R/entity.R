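#' Build a molecular entity from an atom table
#'
#' Constructs an \linkS4class{EntityHandle} from a flat atom table.  Rows
#' are grouped into residues by consecutive runs of the same
#' \code{(chain, resnum, icode)} key and into chains by consecutive runs
#' of the same chain name.  A chain name or residue key that re-appears
#' after a different one is a duplicate and raises an error, as does a
#' repeated atom name within one residue.  Bonds are empty until a
#' connectivity processor (\code{\link{ruleBasedProcess}},
#' \code{\link{heuristicProcess}}) is run.
#'
#' @param atomTable data.frame with columns \code{chain}, \code{resname},
#'   \code{resnum}, \code{name}, \code{element}, \code{x}, \code{y},
#'   \code{z} and optionally \code{icode}, \code{occ}, \code{bfac},
#'   \code{charge}, \code{ishetatm}.
#' @param name entity name.
#' @return an \linkS4class{EntityHandle}.
#' @examples
#' ent <- createEntity(data.frame(
#'   chain = "A", resname = "ALA", resnum = 1,
#'   name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
#'   x = c(0, 1.46, 2.0, 1.5), y = c(0, 0, 1.3, 2.4), z = 0))
#' atomCount(ent)
#' @export
createEntity <- function(atomTable, name = "") {
  at <- as.data.frame(atomTable, stringsAsFactors = FALSE)
  n <- nrow(at)
  req <- c("chain", "resname", "resnum", "name", "element", "x", "y", "z")
  miss <- setdiff(req, names(at))
  if (length(miss)) stop("atomTable lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(at$icode)) at$icode <- rep("", n)
  if (is.null(at$occ)) at$occ <- rep(1.0, n)
  if (is.null(at$bfac)) at$bfac <- rep(0.0, n)
  if (is.null(at$charge)) at$charge <- rep(0.0, n)
  if (is.null(at$ishetatm)) at$ishetatm <- rep(FALSE, n)
  at$chain <- as.character(at$chain); at$resname <- as.character(at$resname)
  at$name <- as.character(at$name); at$element <- as.character(at$element)
  at$icode <- as.character(at$icode); at$resnum <- as.integer(at$resnum)
  pos <- cbind(as.numeric(at$x), as.numeric(at$y), as.numeric(at$z))
  if (n && !all(is.finite(pos))) stop("atom positions must be finite")

  env <- new.env(parent = emptyenv())
  env$name <- name
  env$generation <- 1L
  env$props <- new.env(parent = emptyenv())
  if (n == 0L) {
    env$atoms <- data.frame(id = integer(), chainId = integer(),
      resId = integer(), chain = character(), resname = character(),
      resnum = integer(), icode = character(), name = character(),
      element = character(), occ = numeric(), bfac = numeric(),
      charge = numeric(), ishetatm = logical(), stringsAsFactors = FALSE)
    env$pos <- matrix(numeric(), 0, 3)
    env$residues <- data.frame(resId = integer(), chainId = integer(),
      chain = character(), resname = character(), resnum = integer(),
      icode = character(), olc = character(), chemClass = character(),
      isProtein = logical(), stringsAsFactors = FALSE)
    env$chains <- data.frame(chainId = integer(), chain = character(),
      stringsAsFactors = FALSE)
    env$bonds <- .emptyBonds()
    return(new("EntityHandle", ptr = env))
  }

  # consecutive-run grouping; re-appearance after a different run = duplicate
  chainRun <- cumsum(c(TRUE, at$chain[-1] != at$chain[-n]))
  firstOfRun <- !duplicated(chainRun)
  if (anyDuplicated(at$chain[firstOfRun]))
    stop("duplicate chain name: ",
         at$chain[firstOfRun][duplicated(at$chain[firstOfRun])][1])
  reskey <- paste(at$chain, at$resnum, at$icode, sep = "\r")
  resRun <- cumsum(c(TRUE, reskey[-1] != reskey[-n]))
  firstRes <- !duplicated(resRun)
  if (anyDuplicated(reskey[firstRes])) {
    d <- reskey[firstRes][duplicated(reskey[firstRes])][1]
    stop("duplicate residue number+insertion code in chain: ",
         gsub("\r", " ", d))
  }
  akey <- paste(reskey, at$name, sep = "\r")
  if (anyDuplicated(akey))
    stop("duplicate atom name within residue: ",
         gsub("\r", " ", akey[duplicated(akey)][1]))

  at$id <- seq_len(n)
  at$resId <- resRun
  at$chainId <- chainRun
  firstResIdx <- which(firstRes)
  env$residues <- data.frame(resId = resRun[firstResIdx],
    chainId = chainRun[firstResIdx], chain = at$chain[firstResIdx],
    resname = at$resname[firstResIdx], resnum = at$resnum[firstResIdx],
    icode = at$icode[firstResIdx], olc = "X", chemClass = "unknown",
    isProtein = FALSE, stringsAsFactors = FALSE)
  fc <- which(firstOfRun)
  env$chains <- data.frame(chainId = chainRun[fc], chain = at$chain[fc],
                           stringsAsFactors = FALSE)
  env$atoms <- at[, c("id", "chainId", "resId", "chain", "resname", "resnum",
                      "icode", "name", "element", "occ", "bfac", "charge",
                      "ishetatm")]
  rownames(env$atoms) <- NULL
  env$pos <- pos
  env$bonds <- .emptyBonds()
  new("EntityHandle", ptr = env)
}

.emptyBonds <- function()
  data.frame(a = integer(), b = integer(), order = integer())

.handleOf <- function(x) {
  if (is(x, "EntityHandle")) x
  else if (is(x, "EntityView")) x@handle
  else stop("expected an EntityHandle or EntityView")
}

.checkGeneration <- function(view) {
  if (view@generation != view@handle@ptr$generation)
    stop("stale EntityView: the underlying entity was structurally modified")
  invisible(TRUE)
}

.atomIdsOf <- function(x) {
  if (is(x, "EntityHandle")) x@ptr$atoms$id
  else { .checkGeneration(x); x@atomIds }
}

#' Entity and view accessors
#'
#' \code{atoms} returns the atom table (id, chain/residue membership, name,
#' element, occupancy, B factor, charge, HETATM flag) of a handle or view;
#' \code{positions} the n x 3 coordinate matrix (Angstrom); \code{bonds}
#' the bond table (atom ids \code{a}, \code{b} and bond \code{order}).
#' For a view all three are restricted to the view's atoms; bonds are
#' included only when both endpoints are in the view.  \code{residues}
#' and \code{chainNames} summarise the residue and chain levels;
#' \code{atomCount}, \code{residueCount}, \code{chainCount} and
#' \code{bondCount} count them.
#'
#' @param x an \linkS4class{EntityHandle} or \linkS4class{EntityView}.
#' @return data.frame, matrix or vector as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
atoms <- function(x) {
  h <- .handleOf(x); ids <- .atomIdsOf(x)
  h@ptr$atoms[match(ids, h@ptr$atoms$id), , drop = FALSE]
}

#' @rdname accessors
#' @export
positions <- function(x) {
  h <- .handleOf(x); ids <- .atomIdsOf(x)
  h@ptr$pos[match(ids, h@ptr$atoms$id), , drop = FALSE]
}

#' @rdname accessors
#' @export
bonds <- function(x) {
  h <- .handleOf(x)
  b <- h@ptr$bonds
  if (is(x, "EntityView")) {
    .checkGeneration(x)
    b <- b[b$a %in% x@atomIds & b$b %in% x@atomIds, , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

#' @rdname accessors
#' @export
residues <- function(x) {
  h <- .handleOf(x)
  r <- h@ptr$residues
  if (is(x, "EntityView")) {
    r <- r[r$resId %in% unique(atoms(x)$resId), , drop = FALSE]
    rownames(r) <- NULL
  }
  r
}

#' @rdname accessors
#' @export
chainNames <- function(x) unique(atoms(x)$chain)

#' @rdname accessors
#' @export
atomCount <- function(x) length(.atomIdsOf(x))

#' @rdname accessors
#' @export
residueCount <- function(x) length(unique(atoms(x)$resId))

#' @rdname accessors
#' @export
chainCount <- function(x) length(unique(atoms(x)$chainId))

#' @rdname accessors
#' @export
bondCount <- function(x) nrow(bonds(x))

#' Set atom coordinates on the handle
#'
#' Overwrites the coordinates of the given atoms (all atoms by default) of
#' the underlying handle.  Every view of the handle sees the new positions
#' immediately.
#'
#' @param x handle or view (a view moves exactly its own atoms).
#' @param pos n x 3 numeric matrix, Angstrom.
#' @return the handle, invisibly.
#' @export
setPositions <- function(x, pos) {
  h <- .handleOf(x); ids <- .atomIdsOf(x)
  pos <- as.matrix(pos)
  if (nrow(pos) != length(ids) || ncol(pos) != 3L)
    stop("pos must be a ", length(ids), " x 3 matrix")
  if (length(ids) && !all(is.finite(pos))) stop("positions must be finite")
  h@ptr$pos[match(ids, h@ptr$atoms$id), ] <- pos
  invisible(h)
}

#' Delete atoms from an entity
#'
#' Removes atoms (and any bonds touching them) from the handle.  This is a
#' structural modification: the handle's generation counter is bumped and
#' every existing view of the handle becomes stale (access raises an
#' error).  Residues and chains left without atoms are dropped.
#'
#' @param entity an \linkS4class{EntityHandle}.
#' @param ids atom ids to remove.
#' @return the handle, invisibly.
#' @export
deleteAtoms <- function(entity, ids) {
  e <- .handleOf(entity)@ptr
  ids <- as.integer(ids)
  if (!all(ids %in% e$atoms$id)) stop("unknown atom id(s)")
  keep <- !(e$atoms$id %in% ids)
  e$atoms <- e$atoms[keep, , drop = FALSE]; rownames(e$atoms) <- NULL
  e$pos <- e$pos[keep, , drop = FALSE]
  e$bonds <- e$bonds[!(e$bonds$a %in% ids | e$bonds$b %in% ids), , drop = FALSE]
  e$residues <- e$residues[e$residues$resId %in% e$atoms$resId, , drop = FALSE]
  e$chains <- e$chains[e$chains$chainId %in% e$atoms$chainId, , drop = FALSE]
  e$generation <- e$generation + 1L
  invisible(entity)
}

#' Assemble a view from an explicit atom set
#'
#' Builds the minimal \linkS4class{EntityView} containing exactly the given
#' atoms, their parent residues/chains, and every bond of the handle whose
#' two endpoints are both included.  Complements the query language for
#' selections that are easier to express by looping over atoms.
#'
#' @param entity an \linkS4class{EntityHandle} (or a view; the result still
#'   references the underlying handle).
#' @param atomIds integer atom ids (order preserved, duplicates dropped).
#' @return an \linkS4class{EntityView}.
#' @export
createView <- function(entity, atomIds) {
  h <- .handleOf(entity)
  if (is(entity, "EntityView")) .checkGeneration(entity)
  ids <- as.integer(atomIds)
  ids <- ids[!duplicated(ids)]
  if (!all(ids %in% h@ptr$atoms$id)) stop("atom id(s) not part of this entity")
  if (is(entity, "EntityView") && !all(ids %in% entity@atomIds))
    stop("atom id(s) not part of the source view")
  new("EntityView", handle = h, atomIds = ids,
      generation = h@ptr$generation)
}

#' Promote a handle to (or re-root a view as) a full view
#' @param x handle or view.
#' @return an \linkS4class{EntityView} covering all atoms of \code{x}.
#' @export
asView <- function(x) {
  if (is(x, "EntityView")) return(x)
  createView(x, x@ptr$atoms$id)
}

# ---- generic properties ------------------------------------------------

.propKey <- function(level, id, key) {
  switch(level,
    entity  = paste0("e\r", key),
    atom    = paste0("a", id, "\r", key),
    residue = paste0("r", id, "\r", key),
    chain   = paste0("c", id, "\r", key),
    bond    = paste0("b", id, "\r", key),
    stop("unknown property level: ", level))
}

.propType <- function(value) {
  if (is.character(value)) "text"
  else if (is.logical(value)) "boolean"
  else if (is.integer(value)) "integer"
  else if (is.numeric(value)) "real"
  else stop("unsupported property type: ", class(value)[1])
}

#' Generic key-value properties
#'
#' Any structural element (the entity itself, a chain, residue, atom or
#' bond) can carry typed key-value annotations, e.g. a per-residue
#' conservation score.  Values are strictly typed (\code{text},
#' \code{real}, \code{integer}, \code{boolean}); retrieving a key while
#' asserting the wrong type is an error, as is retrieving an absent key
#' without a default.  Keys are case sensitive.  Properties are stored on
#' the handle, so a view exposes exactly the properties of its handle, and
#' they are queryable from the selection language through the
#' \code{ga:}/\code{gr:}/\code{gc:} prefixes (see \code{\link{select}}).
#'
#' @param x handle or view.
#' @param key property name.
#' @param value scalar character/numeric/integer/logical.
#' @param level one of \code{"entity"}, \code{"chain"}, \code{"residue"},
#'   \code{"atom"}, \code{"bond"}.
#' @param id element id at that level (\code{chainId}, \code{resId}, atom
#'   id, or bond row index); ignored for level \code{"entity"}.
#' @param default value returned when the key is absent; omitting it makes
#'   an absent key an error.
#' @param type optional type assertion: \code{"text"}, \code{"real"},
#'   \code{"integer"} or \code{"boolean"}.
#' @return \code{getProp} returns the stored value; \code{setProp} the
#'   handle, invisibly; \code{hasProp} a logical.
#' @examples
#' ent <- makePolyalaHelix(3)
#' rid <- residues(ent)$resId[1]
#' setProp(ent, "conservation", 0.8, level = "residue", id = rid)
#' getProp(ent, "conservation", level = "residue", id = rid)
#' @name genericProps
NULL

#' @rdname genericProps
#' @export
setProp <- function(x, key, value, level = "entity", id = NULL) {
  h <- .handleOf(x)
  if (length(value) != 1L) stop("property values are scalars")
  if (level != "entity" && is.null(id)) stop("id required for level ", level)
  k <- .propKey(level, id, key)
  assign(k, list(type = .propType(value), value = value), envir = h@ptr$props)
  invisible(h)
}

#' @rdname genericProps
#' @export
getProp <- function(x, key, default, level = "entity", id = NULL,
                    type = NULL) {
  h <- .handleOf(x)
  if (level != "entity" && is.null(id)) stop("id required for level ", level)
  k <- .propKey(level, id, key)
  if (!exists(k, envir = h@ptr$props, inherits = FALSE)) {
    if (missing(default)) stop("no generic property '", key, "' at level ",
                               level, " and no default given")
    return(default)
  }
  rec <- get(k, envir = h@ptr$props, inherits = FALSE)
  if (!is.null(type) && rec$type != type)
    stop("generic property '", key, "' has type ", rec$type, ", not ", type)
  rec$value
}

#' @rdname genericProps
#' @export
hasProp <- function(x, key, level = "entity", id = NULL) {
  h <- .handleOf(x)
  exists(.propKey(level, id, key), envir = h@ptr$props, inherits = FALSE)
}

# ---- spatial search ----------------------------------------------------

#' Find atoms within a radius of a point
#'
#' Returns the ids of all atoms of \code{x} whose Euclidean distance to
#' \code{center} is at most \code{radius}.  Candidate atoms are located
#' with a uniform grid (cell size = radius) so only the 27 cells around
#' the query point are scanned; the result is identical to an exhaustive
#' distance scan.
#'
#' @param x handle or view (a view restricts the search to its atoms).
#' @param center numeric length-3 point, Angstrom.
#' @param radius search radius, Angstrom (>= 0).
#' @return integer vector of atom ids, ascending.
#' @export
findWithin <- function(x, center, radius) {
  if (!is.numeric(center) || length(center) != 3L)
    stop("center must be a numeric length-3 vector")
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a single non-negative number")
  ids <- .atomIdsOf(x)
  if (!length(ids)) return(integer())
  pos <- positions(x)
  grid <- .buildGrid(pos, max(radius, 1e-9))
  cand <- .gridCandidates(grid, center)
  if (!length(cand)) return(integer())
  d2 <- (pos[cand, 1] - center[1])^2 + (pos[cand, 2] - center[2])^2 +
        (pos[cand, 3] - center[3])^2
  sort(ids[cand[d2 <= radius^2 + 1e-12]])
}

.buildGrid <- function(pos, cell) {
  key <- paste(floor(pos[, 1] / cell), floor(pos[, 2] / cell),
               floor(pos[, 3] / cell))
  list(cell = cell, index = split(seq_len(nrow(pos)), key))
}

.gridCandidates <- function(grid, center) {
  c0 <- floor(center / grid$cell)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keys <- paste(c0[1] + off[, 1], c0[2] + off[, 2], c0[3] + off[, 3])
  unlist(grid$index[keys], use.names = FALSE)
}

# multi-point proximity: atoms of x within radius of ANY reference point
.withinAnyOf <- function(x, refPos, radius) {
  ids <- .atomIdsOf(x)
  if (!length(ids) || !nrow(refPos)) return(integer())
  pos <- positions(x)
  hit <- rep(FALSE, length(ids))
  grid <- .buildGrid(pos, max(radius, 1e-9))
  for (i in seq_len(nrow(refPos))) {
    cand <- .gridCandidates(grid, refPos[i, ])
    cand <- cand[!hit[cand]]
    if (!length(cand)) next
    d2 <- (pos[cand, 1] - refPos[i, 1])^2 + (pos[cand, 2] - refPos[i, 2])^2 +
          (pos[cand, 3] - refPos[i, 3])^2
    hit[cand[d2 <= radius^2 + 1e-12]] <- TRUE
  }
  sort(ids[hit])
}

#' Add a bond between two atoms
#'
#' Connectivity is normally derived by \code{\link{ruleBasedProcess}} or
#' \code{\link{heuristicProcess}}; \code{addBond} covers manual editing.
#' Bonds are unordered pairs of distinct atoms of the same entity;
#' duplicates are ignored.
#'
#' @param entity an \linkS4class{EntityHandle}.
#' @param a,b atom ids.
#' @param order bond order (small integer).
#' @return the handle, invisibly.
#' @export
addBond <- function(entity, a, b, order = 1L) {
  e <- .handleOf(entity)@ptr
  a <- as.integer(a); b <- as.integer(b)
  if (a == b) stop("a bond must connect two distinct atoms")
  if (!all(c(a, b) %in% e$atoms$id))
    stop("bond endpoint(s) not part of this entity")
  .addBonds(e, a, b, order)
  invisible(entity)
}

#' Apply a rigid (or general affine) transform to atoms
#'
#' Sets each selected atom position to \code{rotation \%*\% pos +
#' translation} on the handle; views reflect the move.
#'
#' @param x handle or view (a view transforms only its atoms).
#' @param rotation 3x3 matrix.
#' @param translation length-3 vector.
#' @return the handle, invisibly.
#' @export
applyTransform <- function(x, rotation, translation = c(0, 0, 0)) {
  p <- positions(x)
  setPositions(x, sweep(p %*% t(rotation), 2, -translation))
}
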