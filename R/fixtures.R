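# Synthetic structure generators.  Everything the test surface needs is
# built from code: no fixture requires a download.

.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
  }
  force(code)
}

# place atom D from A, B, C with bond |C-D|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg); the standard internal-coordinate (NeRF) step
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * cos(dih) * sin(ang),
          -bond * sin(dih) * sin(ang))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cbind(bc, .cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

.cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

.buildBackbone <- function(resnames, phi = -57, psi = -47, omega = 180) {
  n <- length(resnames)
  rows <- list()
  # ideal backbone internal coordinates (Engh-Huber-like values)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231; bCACB <- 1.53
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.8
  aNCACB <- 110.5
  pos <- list()
  for (i in seq_len(n)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(bNCA, 0, 0)
      C <- .placeAtom(c(0, 0, 1), N, CA, bCAC, aNCAC, 60)
    } else {
      p <- pos[[i - 1L]]
      N <- .placeAtom(p$N, p$CA, p$C, bCN, aCACN, psi)
      CA <- .placeAtom(p$CA, p$C, N, bNCA, aCNCA, omega)
      C <- .placeAtom(p$C, N, CA, bCAC, aNCAC, phi)
    }
    O <- .placeAtom(N, CA, C, bCO, aCACO, if (i < n) psi + 180 else psi)
    CB <- .placeAtom(N, C, CA, bCACB, aNCACB, -122.6)
    pos[[i]] <- list(N = N, CA = CA, C = C, O = O, CB = CB)
    atomNames <- if (resnames[i] == "GLY") c("N", "CA", "C", "O")
                 else c("N", "CA", "C", "O", "CB")
    for (an in atomNames) {
      p3 <- pos[[i]][[an]]
      rows[[length(rows) + 1L]] <- data.frame(chain = "A",
        resname = resnames[i], resnum = i, name = an,
        element = substr(an, 1, 1), x = p3[1], y = p3[2], z = p3[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic structure fixtures
#'
#' \code{makePolyalaHelix} builds an ideal poly-alanine alpha-helix
#' (backbone dihedrals phi = -57, psi = -47 degrees, standard bond
#' lengths/angles) with N, CA, C, O, CB atoms per residue in chain A;
#' consecutive CA-CA distances come out at ~3.8 Angstrom and peptide
#' C(i)-N(i+1) bonds at 1.33 Angstrom, so connectivity processing finds
#' exactly n-1 peptide bonds.  \code{makeDipeptide} is the two-residue
#' case with selectable residue names.  \code{makePointCloud} builds an
#' entity of \code{n} atoms with random coordinates, elements and
#' residue/chain assignment -- the workhorse for query-language and
#' proximity property tests.  All generators are deterministic given
#' \code{seed} and leave the caller's RNG state untouched.
#'
#' @param n,nResidues size of the fixture.
#' @param seed integer seed (the helix itself is deterministic; the seed
#'   only matters when \code{noiseSigma > 0}).
#' @param noiseSigma Gaussian positional jitter, Angstrom.
#' @param resnames residue names for \code{makeDipeptide}.
#' @param box edge length of the cubic region point-cloud atoms fall in.
#' @param elements element pool sampled for point-cloud atoms.
#' @return an \linkS4class{EntityHandle}.
#' @examples
#' h <- makePolyalaHelix(10)
#' atomCount(h)  # 50
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
makePolyalaHelix <- function(nResidues, seed = 1L, noiseSigma = 0) {
  if (nResidues < 1L) stop("nResidues must be >= 1")
  df <- .buildBackbone(rep("ALA", nResidues))
  if (noiseSigma > 0)
    df[, c("x", "y", "z")] <- .withSeed(seed,
      df[, c("x", "y", "z")] + rnorm(3L * nrow(df), sd = noiseSigma))
  createEntity(df, name = sprintf("polyALA%d", nResidues))
}

#' @rdname fixtures
#' @export
makeDipeptide <- function(resnames = c("ALA", "GLY")) {
  stopifnot(length(resnames) == 2L)
  createEntity(.buildBackbone(resnames), name = "dipeptide")
}

#' @rdname fixtures
#' @export
makePointCloud <- function(n, seed = 1L, box = 20,
                           elements = c("C", "N", "O", "S", "FE")) {
  if (n < 1L) stop("n must be >= 1")
  .withSeed(seed, {
    nres <- max(1L, ceiling(n / 4))
    resOfAtom <- sort(sample.int(nres, n, replace = TRUE))
    resnamePool <- c("LIG", "UNL", "XXX", "HOH", "HEM")
    resnames <- sample(resnamePool, nres, replace = TRUE)
    chainOfRes <- sample(c("A", "B"), nres, replace = TRUE)
    ord <- order(chainOfRes, seq_len(nres))  # contiguous chains
    rank <- match(seq_len(nres), ord)
    df <- data.frame(chain = chainOfRes[resOfAtom],
      resname = resnames[resOfAtom], resnum = resOfAtom,
      name = paste0("X", seq_len(n)),
      element = sample(elements, n, replace = TRUE, prob = c(6, 2, 2, 1, 1)),
      x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
      occ = round(runif(n), 2), bfac = round(runif(n, 0, 100), 2),
      charge = sample(c(-1, 0, 0, 0, 1), n, replace = TRUE),
      ishetatm = sample(c(TRUE, FALSE), n, replace = TRUE),
      stringsAsFactors = FALSE)
    df <- df[order(rank[resOfAtom]), , drop = FALSE]
    createEntity(df, name = sprintf("cloud%d", n))
  })
}

#' Synthetic trajectories with a closed-form descriptor
#'
#' Writes a CHARMM DCD file whose frames displace the entity's coordinates
#' according to a known motion: \code{"sinusoid"} translates all atoms
#' rigidly along x by \code{amplitude * sin(2*pi*(t-1)/period)} for frame
#' t (so the centroid displacement is analytic), \code{"brownian"} adds
#' cumulative Gaussian steps (sd \code{amplitude} per frame per
#' coordinate).  Deterministic per seed.
#'
#' @param entity topology whose current coordinates are frame 1's base.
#' @param path output DCD path.
#' @param nFrames number of frames (>= 1).
#' @param motion \code{"sinusoid"} or \code{"brownian"}.
#' @param amplitude Angstrom.
#' @param period frames per sinusoid cycle.
#' @param seed RNG seed (brownian motion).
#' @return invisibly, the matrix (nFrames x 3) of centroid positions
#'   actually written.
#' @export
makeTrajectory <- function(entity, path, nFrames = 10L,
                           motion = c("sinusoid", "brownian"),
                           amplitude = 1.0, period = 10, seed = 1L) {
  motion <- match.arg(motion)
  if (nFrames < 1L) stop("nFrames must be >= 1")
  base <- positions(entity)
  frames <- vector("list", nFrames)
  if (motion == "sinusoid") {
    for (t in seq_len(nFrames)) {
      dx <- amplitude * sin(2 * pi * (t - 1) / period)
      f <- base; f[, 1] <- f[, 1] + dx
      frames[[t]] <- f
    }
  } else {
    .withSeed(seed, {
      drift <- matrix(0, nrow(base), 3)
      for (t in seq_len(nFrames)) {
        drift <- drift + matrix(rnorm(length(base), sd = amplitude),
                                nrow(base), 3)
        frames[[t]] <- base + drift
      }
    })
  }
  writeDCD(frames, path)
  cent <- t(vapply(frames, colMeans, numeric(3)))
  invisible(cent)
}
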