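# Domain-aware images and electron-density maps.

#' Create an image handle
#'
#' Wraps a 1/2/3-D numeric (or complex) array as an
#' \linkS4class{ImageHandle} with sampling metadata.  The \code{sampling}
#' slot always stores the spatial pixel size (Angstrom per pixel); voxel
#' \code{(i, j, k)} (1-based) is centred at \code{origin + (i-1, j-1,
#' k-1) * sampling}.
#'
#' @param data numeric or complex vector/array.
#' @param sampling Angstrom per pixel, scalar or per dimension.
#' @param origin spatial position of the first voxel centre.
#' @param domain \code{"spatial"} or \code{"frequency"}.
#' @param conjugateSymmetric frequency-domain only: buffer is the
#'   transform of a real image.
#' @return an \linkS4class{ImageHandle}.
#' @export
imageHandle <- function(data, sampling = 1, origin = c(0, 0, 0),
                        domain = "spatial", conjugateSymmetric = FALSE) {
  if (is.null(dim(data))) dim(data) <- length(data)
  d <- length(dim(data))
  sampling <- rep_len(sampling, d)
  origin <- rep_len(origin, d)
  new("ImageHandle", data = data, sampling = sampling, origin = origin,
      domain = domain, conjugateSymmetric = conjugateSymmetric)
}

#' Image accessors
#' @param img an \linkS4class{ImageHandle}.
#' @name imageAccessors
NULL

#' @rdname imageAccessors
#' @export
imageData <- function(img) img@data

#' @rdname imageAccessors
#' @export
imageSampling <- function(img) img@sampling

#' @rdname imageAccessors
#' @export
imageOrigin <- function(img) img@origin

#' @rdname imageAccessors
#' @export
imageDomain <- function(img) img@domain

#' @rdname imageAccessors
#' @export
isConjugateSymmetric <- function(img)
  img@domain == "frequency" && img@conjugateSymmetric

#' Fourier transform with domain tracking
#'
#' Applies the discrete Fourier transform and toggles the image's active
#' domain.  The convention is forward unscaled, inverse divided by the
#' number of elements, so \code{fftImage(fftImage(x))} returns \code{x}.
#' Transforming a real spatial image marks the resulting frequency buffer
#' conjugate symmetric; transforming a conjugate-symmetric frequency
#' image back yields a real spatial image, while a frequency image
#' without that symmetry transforms to a complex spatial image.
#'
#' @param img an \linkS4class{ImageHandle}.
#' @return the transformed \linkS4class{ImageHandle}.
#' @export
fftImage <- function(img) {
  if (img@domain == "spatial") {
    realIn <- !is.complex(img@data)
    out <- stats::fft(img@data)
    imageHandle(out, img@sampling, img@origin, domain = "frequency",
                conjugateSymmetric = realIn)
  } else {
    out <- stats::fft(img@data, inverse = TRUE) / length(img@data)
    if (img@conjugateSymmetric) out <- array(Re(out), dim(out))
    imageHandle(out, img@sampling, img@origin, domain = "spatial")
  }
}

# |k|^2 array in (cycles/Angstrom)^2 for the FFT layout of dims/sampling
.freqSq <- function(dims, sampling) {
  axes <- lapply(seq_along(dims), function(i) {
    n <- dims[i]
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / (n * sampling[i])
    k^2
  })
  g <- array(0, dims)
  for (i in seq_along(dims))
    g <- g + array(axes[[i]][slice.index(g, i)], dims)
  g
}

.spatialFilter <- function(img, factorFun) {
  if (img@domain != "spatial")
    stop("filters expect a spatial-domain image")
  f <- fftImage(img)
  k2 <- .freqSq(dim(f@data), img@sampling)
  out <- f@data * factorFun(k2)
  back <- stats::fft(out, inverse = TRUE) / length(out)
  if (!is.complex(img@data)) back <- array(Re(back), dim(back))
  imageHandle(back, img@sampling, img@origin)
}

#' Spatial filters
#'
#' All filters take a spatial-domain image, operate in frequency space
#' and return a spatial-domain image.  \code{gaussianBlur} multiplies the
#' spectrum by \code{exp(-2 pi^2 sigma^2 |k|^2)} (the transform of a
#' unit-integral Gaussian kernel of width \code{sigma}), so the mean
#' intensity (DC term) is preserved.  \code{lowPass} zeroes all spatial
#' frequencies above \code{1/cutoff}; \code{highPass} zeroes those below.
#' \code{applyMask} multiplies voxelwise with a mask (an image on the
#' same grid, or an array).
#'
#' @param img a spatial-domain \linkS4class{ImageHandle}.
#' @param sigma Gaussian width, Angstrom.
#' @param cutoff wavelength cutoff, Angstrom (> 0); frequencies are
#'   compared against \code{1/cutoff}.
#' @param mask \linkS4class{ImageHandle} or array of matching dimensions.
#' @return a spatial-domain \linkS4class{ImageHandle}.
#' @name imageFilters
NULL

#' @rdname imageFilters
#' @export
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  .spatialFilter(img, function(k2) exp(-2 * pi^2 * sigma^2 * k2))
}

#' @rdname imageFilters
#' @export
lowPass <- function(img, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  kc2 <- (1 / cutoff)^2
  .spatialFilter(img, function(k2) as.numeric(k2 <= kc2))
}

#' @rdname imageFilters
#' @export
highPass <- function(img, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  kc2 <- (1 / cutoff)^2
  .spatialFilter(img, function(k2) as.numeric(k2 >= kc2))
}

#' @rdname imageFilters
#' @export
applyMask <- function(img, mask) {
  m <- if (is(mask, "ImageHandle")) mask@data else mask
  if (!identical(dim(img@data), dim(m)))
    stop("mask dimensions do not match the image")
  imageHandle(img@data * m, img@sampling, img@origin, img@domain,
              img@conjugateSymmetric)
}

#' Density-generation parameters
#'
#' @param sigma Gaussian width per atom, Angstrom (> 0).
#' @param amplitude \code{"uniform"} (every atom contributes amplitude 1)
#'   or \code{"element-weighted"} (amplitude = atomic number).
#' @param sampling voxel size, Angstrom (> 0).
#' @param padding margin added around the structure's bounding box,
#'   Angstrom.
#' @param cutoffSigma per-atom evaluation radius in units of sigma;
#'   contributions beyond it are dropped (the default 5 keeps the
#'   truncation error below 4e-6 of an atom's peak).
#' @return parameter list for \code{\link{entityToDensity}}.
#' @export
densityParams <- function(sigma = 1.5, amplitude = c("uniform",
                          "element-weighted"), sampling = 1.0,
                          padding = 3 * sigma, cutoffSigma = 5) {
  amplitude <- match.arg(amplitude)
  if (sigma <= 0) stop("sigma must be > 0")
  if (sampling <= 0) stop("sampling must be > 0")
  list(sigma = sigma, amplitude = amplitude, sampling = sampling,
       padding = padding, cutoffSigma = cutoffSigma)
}

.atomicNumbers <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, FE = 26)

#' Convert a structure to a density map
#'
#' Places a Gaussian sphere of width \code{sigma} at every atom position:
#' the map value at a voxel centre v is \code{sum_a A_a * exp(-|v -
#' pos_a|^2 / (2 sigma^2))}, evaluated within \code{cutoffSigma * sigma}
#' of each atom (the Gaussian is separable, so each atom adds an outer
#' product of per-axis profiles).  By default the grid covers the
#' structure's bounding box plus \code{padding} on every side and the
#' origin is recorded so the voxel-to-Angstrom mapping is exact;
#' alternatively pass \code{grid} to evaluate on an existing map's grid
#' (e.g. the experimental map a fragment is scored against).
#'
#' @param view \linkS4class{EntityView} or handle (non-empty).
#' @param params see \code{\link{densityParams}}.
#' @param grid optional \linkS4class{ImageHandle} whose size/sampling/
#'   origin define the output grid.
#' @return a spatial-domain \linkS4class{ImageHandle}.
#' @export
entityToDensity <- function(view, params = densityParams(), grid = NULL) {
  pos <- positions(view)
  if (!nrow(pos)) stop("cannot compute density of an empty view")
  sg <- params$sigma
  amp <- if (params$amplitude == "uniform") rep(1, nrow(pos)) else {
    z <- .atomicNumbers[toupper(atoms(view)$element)]
    ifelse(is.na(z), 6, z)
  }
  if (is.null(grid)) {
    lo <- apply(pos, 2, min) - params$padding
    hi <- apply(pos, 2, max) + params$padding
    sampling <- rep(params$sampling, 3)
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / sampling)) + 1L)
    origin <- lo
  } else {
    dims <- dim(grid@data); sampling <- grid@sampling; origin <- grid@origin
  }
  vox <- array(0, dims)
  cut <- params$cutoffSigma * sg
  axisCoord <- lapply(1:3, function(i)
    origin[i] + (seq_len(dims[i]) - 1) * sampling[i])
  for (a in seq_len(nrow(pos))) {
    w <- vector("list", 3)
    ok <- TRUE
    for (i in 1:3) {
      idx <- which(abs(axisCoord[[i]] - pos[a, i]) <= cut)
      if (!length(idx)) { ok <- FALSE; break }
      w[[i]] <- list(idx = idx,
                     g = exp(-(axisCoord[[i]][idx] - pos[a, i])^2 /
                             (2 * sg^2)))
    }
    if (!ok) next
    blk <- amp[a] * (w[[1]]$g %o% w[[2]]$g %o% w[[3]]$g)
    vox[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] <-
      vox[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] + blk
  }
  imageHandle(vox, sampling, origin)
}

# geometric footprint: voxels within `radius` of any atom of the view
.footprintMask <- function(view, grid, radius) {
  pos <- positions(view)
  dims <- dim(grid@data); sampling <- grid@sampling; origin <- grid@origin
  m <- array(FALSE, dims)
  axisCoord <- lapply(1:3, function(i)
    origin[i] + (seq_len(dims[i]) - 1) * sampling[i])
  for (a in seq_len(nrow(pos))) {
    idx <- lapply(1:3, function(i)
      which(abs(axisCoord[[i]] - pos[a, i]) <= radius))
    if (any(!lengths(idx))) next
    d2 <- outer(outer((axisCoord[[1]][idx[[1]]] - pos[a, 1])^2,
                      (axisCoord[[2]][idx[[2]]] - pos[a, 2])^2, "+"),
                (axisCoord[[3]][idx[[3]]] - pos[a, 3])^2, "+")
    m[idx[[1]], idx[[2]], idx[[3]]] <-
      m[idx[[1]], idx[[2]], idx[[3]]] | (d2 <= radius^2)
  }
  m
}

#' Real-space cross-correlation of two maps
#'
#' Pearson correlation of the voxel values of two spatial-domain maps:
#' \code{sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))}, over the whole (congruent) grid or a logical
#' \code{region} mask.  Maps on different grids are first brought onto
#' the first map's grid by trilinear interpolation.  The value is
#' invariant under any positive affine rescaling of either map.
#'
#' @param mapA,mapB spatial-domain \linkS4class{ImageHandle}s.
#' @param region optional logical array (on \code{mapA}'s grid) selecting
#'   the voxels to correlate over.
#' @return correlation in [-1, 1].
#' @export
realSpaceCorrelation <- function(mapA, mapB, region = NULL) {
  if (mapA@domain != "spatial" || mapB@domain != "spatial")
    stop("real-space correlation expects spatial-domain maps")
  if (!identical(dim(mapA@data), dim(mapB@data)) ||
      max(abs(mapA@sampling - mapB@sampling)) > 1e-6 ||
      max(abs(mapA@origin - mapB@origin)) > 1e-6) {
    mapB <- resampleImage(mapB, mapA)
  }
  a <- as.numeric(mapA@data); b <- as.numeric(mapB@data)
  if (!is.null(region)) {
    sel <- as.logical(region)
    if (length(sel) != length(a)) stop("region mask size mismatch")
    a <- a[sel]; b <- b[sel]
  }
  if (!length(a)) stop("empty correlation region")
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va == 0 || vb == 0) stop("zero-variance input to correlation")
  sum(a * b) / sqrt(va * vb)
}

#' Resample a map onto another map's grid (trilinear)
#'
#' @param img map to resample (3-D, spatial domain).
#' @param like map whose size/sampling/origin define the target grid.
#' @return \linkS4class{ImageHandle} on \code{like}'s grid; voxels
#'   falling outside \code{img} are 0.
#' @export
resampleImage <- function(img, like) {
  dims <- dim(like@data)
  src <- img@data
  sdim <- dim(src)
  out <- array(0, dims)
  # fractional source indices of every target voxel centre, per axis
  ax <- lapply(1:3, function(i) {
    coord <- like@origin[i] + (seq_len(dims[i]) - 1) * like@sampling[i]
    (coord - img@origin[i]) / img@sampling[i] + 1
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  f <- floor(as.matrix(g)); t <- as.matrix(g) - f
  ok <- f[, 1] >= 1 & f[, 1] < sdim[1] & f[, 2] >= 1 & f[, 2] < sdim[2] &
        f[, 3] >= 1 & f[, 3] < sdim[3]
  idx <- function(dx, dy, dz)
    cbind(f[ok, 1] + dx, f[ok, 2] + dy, f[ok, 3] + dz)
  tx <- t[ok, 1]; ty <- t[ok, 2]; tz <- t[ok, 3]
  v <- (1 - tx) * (1 - ty) * (1 - tz) * src[idx(0, 0, 0)] +
       tx * (1 - ty) * (1 - tz) * src[idx(1, 0, 0)] +
       (1 - tx) * ty * (1 - tz) * src[idx(0, 1, 0)] +
       (1 - tx) * (1 - ty) * tz * src[idx(0, 0, 1)] +
       tx * ty * (1 - tz) * src[idx(1, 1, 0)] +
       tx * (1 - ty) * tz * src[idx(1, 0, 1)] +
       (1 - tx) * ty * tz * src[idx(0, 1, 1)] +
       tx * ty * tz * src[idx(1, 1, 1)]
  out[ok] <- v
  imageHandle(out, like@sampling, like@origin)
}

#' Score structure fragments against an experimental map
#'
#' For each candidate fragment, computes its Gaussian-sphere density on
#' the experimental map's grid (\code{\link{entityToDensity}}) and the
#' real-space cross-correlation with the experimental map over the
#' fragment's footprint (voxels within \code{4 * sigma} of any fragment
#' atom); fragments are returned sorted by decreasing correlation.
#'
#' @param fragments list of \linkS4class{EntityView}s (or handles).
#' @param expMap spatial-domain \linkS4class{ImageHandle}.
#' @param params see \code{\link{densityParams}}.
#' @return data.frame with columns \code{fragment} (index into
#'   \code{fragments}) and \code{correlation}, sorted descending.
#' @export
scoreFragments <- function(fragments, expMap, params = densityParams()) {
  if (!length(fragments)) stop("no fragments to score")
  cors <- vapply(fragments, function(fr) {
    fmap <- entityToDensity(fr, params, grid = expMap)
    mask <- .footprintMask(fr, expMap, 4 * params$sigma)
    realSpaceCorrelation(fmap, expMap, region = mask)
  }, numeric(1))
  out <- data.frame(fragment = seq_along(fragments), correlation = cors)
  out[order(-out$correlation), , drop = FALSE]
}

# ---- MRC / CCP4 map I/O ------------------------------------------------

#' Read and write MRC/CCP4 density maps
#'
#' Mode-2 (float32) maps only.  \code{writeMRC} stores the map in
#' canonical x,y,z axis order with cell = extent * sampling and the
#' MRC2014 ORIGIN field; \code{readMRC} honours the MAPC/MAPR/MAPS axis
#' permutation (data are returned in canonical x,y,z order), derives the
#' sampling from cell/grid, and falls back to NXSTART-based origins when
#' the ORIGIN field is zero.  Both byte orders are read (detected from
#' the MODE/MAP fields).  A write-read round trip preserves size,
#' sampling, origin and voxel values exactly (values are stored as
#' float32).
#'
#' @param path file path.
#' @param img a 3-D spatial-domain \linkS4class{ImageHandle}.
#' @return \code{readMRC}: an \linkS4class{ImageHandle}; \code{writeMRC}:
#'   the path, invisibly.
#' @export
readMRC <- function(path) {
  sz <- file.size(path)
  for (endian in c("little", "big")) {
    con <- file(path, "rb")
    nxyz <- readBin(con, "integer", 3, size = 4, endian = endian)
    mode <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (any(is.na(nxyz)) || any(nxyz <= 0) || any(nxyz > 100000L) ||
        is.na(mode) || mode < 0 || mode > 101) { close(con); next }
    nstart <- readBin(con, "integer", 3, size = 4, endian = endian)
    mxyz <- readBin(con, "integer", 3, size = 4, endian = endian)
    cella <- readBin(con, "double", 3, size = 4, endian = endian)
    readBin(con, "double", 3, size = 4, endian = endian)  # cell angles
    mapcrs <- readBin(con, "integer", 3, size = 4, endian = endian)
    readBin(con, "double", 3, size = 4, endian = endian)  # dmin/dmax/dmean
    readBin(con, "integer", 1, size = 4, endian = endian) # ispg
    nsymbt <- readBin(con, "integer", 1, size = 4, endian = endian)
    readBin(con, "raw", 100)                              # extra
    origin <- readBin(con, "double", 3, size = 4, endian = endian)
    mapTag <- rawToChar(readBin(con, "raw", 4))
    close(con)
    if (!grepl("^MAP", mapTag)) next
    if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2)")
    n <- prod(nxyz)
    if (sz < 1024 + nsymbt + 4 * n)
      stop("MRC header/grid inconsistency: file too small for ",
           paste(nxyz, collapse = "x"))
    con <- file(path, "rb")
    readBin(con, "raw", 1024 + nsymbt)
    vals <- readBin(con, "double", n, size = 4, endian = endian)
    close(con)
    disk <- array(vals, nxyz)
    if (!setequal(mapcrs, 1:3))
      stop("MRC header/grid inconsistency: bad MAPC/MAPR/MAPS ",
           paste(mapcrs, collapse = ","))
    canon <- aperm(disk, mapcrs)
    dims <- dim(canon)
    mCanon <- integer(3); mCanon[mapcrs] <- 1:3  # disk slot per canonical axis
    sampling <- cella / mxyz
    if (any(!is.finite(sampling)) || any(sampling <= 0)) sampling <- rep(1, 3)
    nstartCanon <- integer(3)
    nstartCanon[mapcrs] <- nstart
    if (all(abs(origin) < 1e-20) && any(nstartCanon != 0L))
      origin <- nstartCanon * sampling
    return(imageHandle(canon, sampling, origin))
  }
  stop("not a readable MRC/CCP4 map: ", path)
}

#' @rdname readMRC
#' @export
writeMRC <- function(img, path) {
  if (length(dim(img@data)) != 3L) stop("writeMRC expects a 3-D map")
  if (img@domain != "spatial") stop("writeMRC expects a spatial-domain map")
  d <- dim(img@data)
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wF <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  v <- as.numeric(img@data)
  wI(d); wI(2L)                       # nx ny nz, mode 2
  wI(c(0L, 0L, 0L))                   # nstart
  wI(d)                               # mx my mz
  wF(d * img@sampling)                # cell a b c
  wF(c(90, 90, 90))                   # cell angles
  wI(1:3)                             # mapc mapr maps: canonical
  wF(c(min(v), max(v), mean(v)))      # dmin dmax dmean
  wI(c(1L, 0L))                       # ispg, nsymbt
  writeBin(raw(100), con)             # extra
  wF(img@origin)                      # MRC2014 origin
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wF(stats::sd(v))                    # rms
  wI(1L)                              # nlabl
  lab <- sprintf("%-80s", "molkit map")
  writeChar(lab, con, eos = NULL)
  writeBin(raw(80 * 9), con)
  wF(v)
  invisible(path)
}
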