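# CHARMM DCD binary trajectories: 4-byte Fortran record markers, 'CORD'
# magic, 20-int control block, optional per-frame unit-cell record
# (honoured and skipped), single-precision x/y/z blocks.  Endianness is
# detected from the first record marker.

.dcdReadHeader <- function(con) {
  for (endian in c("little", "big")) {
    seek(con, 0)
    m <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (length(m) == 1L && !is.na(m) && m == 84L) {
      magic <- rawToChar(readBin(con, "raw", 4))
      if (magic != "CORD") stop("DCD magic-number mismatch: '", magic, "'")
      icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
      m2 <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (m2 != 84L) stop("DCD header record marker mismatch")
      tl <- readBin(con, "integer", 1, size = 4, endian = endian)
      ntitle <- readBin(con, "integer", 1, size = 4, endian = endian)
      title <- rawToChar(readBin(con, "raw", 80 * ntitle))
      if (readBin(con, "integer", 1, size = 4, endian = endian) != tl)
        stop("DCD title record marker mismatch")
      if (readBin(con, "integer", 1, size = 4, endian = endian) != 4L)
        stop("DCD natom record marker mismatch")
      natom <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (readBin(con, "integer", 1, size = 4, endian = endian) != 4L)
        stop("DCD natom record marker mismatch")
      hasCell <- icntrl[20] > 0L && icntrl[11] == 1L
      if (icntrl[9] != 0L) stop("DCD files with fixed atoms are unsupported")
      return(list(endian = endian, natom = natom, nset = icntrl[1],
                  hasCell = hasCell, title = title,
                  dataStart = seek(con)))
    }
  }
  stop("DCD magic-number mismatch: first record marker is not 84")
}

.dcdFrameBytes <- function(h) {
  cell <- if (h$hasCell) 4 + 48 + 4 else 0
  cell + 3 * (4 + 4 * h$natom + 4)
}

.dcdReadFrameAt <- function(con, h, offset) {
  seek(con, offset)
  if (h$hasCell) {
    if (readBin(con, "integer", 1, size = 4, endian = h$endian) != 48L)
      stop("DCD truncated frame: bad unit-cell marker")
    readBin(con, "double", 6, size = 8, endian = h$endian)
    readBin(con, "integer", 1, size = 4, endian = h$endian)
  }
  out <- matrix(0, h$natom, 3)
  for (k in 1:3) {
    m <- readBin(con, "integer", 1, size = 4, endian = h$endian)
    if (!length(m) || is.na(m) || m != 4L * h$natom)
      stop("DCD truncated frame: bad coordinate record marker")
    v <- readBin(con, "double", h$natom, size = 4, endian = h$endian)
    if (length(v) != h$natom) stop("DCD truncated frame")
    out[, k] <- v
    readBin(con, "integer", 1, size = 4, endian = h$endian)
  }
  out
}

#' Read a CHARMM DCD trajectory
#'
#' Reads a DCD file against a topology entity.  \code{mode = "in_memory"}
#' loads all (strided) frames at once -- recommended for small,
#' preprocessed trajectories.  \code{mode = "lazy"} parses only the
#' header and computes per-frame file offsets; frames are then fetched
#' from disk on demand and kept in a bounded LRU cache, so trajectories
#' larger than memory can be processed.  Both modes return bit-identical
#' coordinates for every frame index.
#'
#' @param path DCD file.
#' @param topology \linkS4class{EntityHandle} with the same atom count as
#'   the file.
#' @param mode \code{"in_memory"} or \code{"lazy"}.
#' @param stride keep every \code{stride}-th frame (>= 1).
#' @param cacheSize maximum number of frames resident in lazy mode.
#' @return a \linkS4class{Trajectory}.
#' @export
readDCD <- function(path, topology, mode = c("in_memory", "lazy"),
                    stride = 1L, cacheSize = 16L) {
  mode <- match.arg(mode)
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .dcdReadHeader(con)
  if (h$natom != atomCount(topology))
    stop("DCD atom count (", h$natom, ") does not match topology (",
         atomCount(topology), ")")
  fb <- .dcdFrameBytes(h)
  avail <- (file.size(path) - h$dataStart) %/% fb
  sel <- seq.int(1L, avail, by = stride)
  offsets <- h$dataStart + (sel - 1L) * fb
  p <- new.env(parent = emptyenv())
  p$natom <- h$natom; p$endian <- h$endian; p$hasCell <- h$hasCell
  p$frameCount <- length(sel); p$stride <- stride; p$mode <- mode
  p$path <- normalizePath(path); p$offsets <- offsets
  p$topology <- topology
  p$fetchCount <- 0L
  p$hdr <- h
  if (mode == "in_memory") {
    p$frames <- lapply(offsets, function(o) .dcdReadFrameAt(con, h, o))
  } else {
    p$cacheSize <- as.integer(cacheSize)
    p$cache <- list()      # frame index -> matrix, insertion = LRU order
  }
  new("Trajectory", ptr = p)
}

#' Trajectory accessors
#'
#' \code{frameCount} and \code{trajAtomCount} report sizes;
#' \code{fetchCount} the number of disk reads a lazy trajectory has
#' performed (in-memory: the initial frame count);
#' \code{residentFrames} how many frames a lazy trajectory currently
#' caches.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @name trajectoryAccessors
NULL

#' @rdname trajectoryAccessors
#' @export
frameCount <- function(traj) traj@ptr$frameCount

#' @rdname trajectoryAccessors
#' @export
trajAtomCount <- function(traj) traj@ptr$natom

#' @rdname trajectoryAccessors
#' @export
fetchCount <- function(traj)
  if (traj@ptr$mode == "lazy") traj@ptr$fetchCount else traj@ptr$frameCount

#' @rdname trajectoryAccessors
#' @export
residentFrames <- function(traj)
  if (traj@ptr$mode == "lazy") length(traj@ptr$cache) else traj@ptr$frameCount

#' Access trajectory frames
#'
#' \code{framePositions} returns frame \code{i} (1-based) as an
#' atom x 3 coordinate matrix (Angstrom); in lazy mode the frame is
#' fetched from disk if not cached.  \code{applyFrame} writes frame
#' \code{i}'s coordinates into an entity (default: the trajectory's
#' topology); every view of that entity sees the move.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param i frame index, 1-based.
#' @param entity entity whose positions are set.
#' @return \code{framePositions}: matrix; \code{applyFrame}: the entity,
#'   invisibly.
#' @export
framePositions <- function(traj, i) {
  p <- traj@ptr
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > p$frameCount)
    stop("frame index out of range [1, ", p$frameCount, "]")
  if (p$mode == "in_memory") return(p$frames[[i]])
  key <- as.character(i)
  if (!is.null(p$cache[[key]])) {
    f <- p$cache[[key]]
    p$cache[[key]] <- NULL        # re-insert at LRU tail
    p$cache[[key]] <- f
    return(f)
  }
  con <- file(p$path, "rb")
  on.exit(close(con))
  f <- .dcdReadFrameAt(con, p$hdr, p$offsets[i])
  p$fetchCount <- p$fetchCount + 1L
  p$cache[[key]] <- f
  while (length(p$cache) > p$cacheSize) p$cache[[1L]] <- NULL
  f
}

#' @rdname framePositions
#' @export
applyFrame <- function(traj, i, entity = traj@ptr$topology) {
  setPositions(entity, framePositions(traj, i))
  invisible(entity)
}

#' Write a CHARMM DCD file
#'
#' Minimal single-precision DCD writer used to build trajectory fixtures
#' (and by the command-line conversion tool).  Writes little-endian
#' CHARMM-dialect files, optionally with a unit-cell record per frame.
#'
#' @param frames list of atom x 3 coordinate matrices, equal sizes.
#' @param path output path.
#' @param cell optional length-6 unit cell written with every frame.
#' @return invisibly, the path.
#' @export
writeDCD <- function(frames, path, cell = NULL) {
  if (!length(frames)) stop("no frames to write")
  natom <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == natom))
    stop("all frames must have the same atom count")
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  icntrl <- integer(20)
  icntrl[1] <- length(frames); icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[4] <- length(frames)
  icntrl[11] <- if (is.null(cell)) 0L else 1L
  icntrl[20] <- 24L  # CHARMM version stamp
  wInt(84); writeChar("CORD", con, eos = NULL); wInt(icntrl); wInt(84)
  title <- sprintf("%-80s", "molkit synthetic trajectory")
  wInt(4 + 80); wInt(1); writeChar(title, con, eos = NULL); wInt(4 + 80)
  wInt(4); wInt(natom); wInt(4)
  for (f in frames) {
    if (!is.null(cell)) {
      wInt(48); writeBin(as.double(cell), con, size = 8, endian = "little")
      wInt(48)
    }
    for (k in 1:3) {
      wInt(4 * natom)
      writeBin(as.double(f[, k]), con, size = 4, endian = "little")
      wInt(4 * natom)
    }
  }
  invisible(path)
}
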