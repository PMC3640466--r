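# Domain-aware images: FT, filters, structure-to-density, correlation,
# MRC maps.

randomMap <- function(dims, seed = 1) {
  set.seed(seed)
  imageHandle(array(rnorm(prod(dims)), dims))
}

test_that("fft toggles domains and tracks conjugate symmetry", {
  x <- randomMap(c(4, 4, 4), 71)
  f <- fftImage(x)
  expect_equal(imageDomain(f), "frequency")
  expect_true(isConjugateSymmetric(f))
  # F(-k) = conj(F(k))
  d <- imageData(f)
  idx <- function(i, n) ifelse(i == 1, 1, n - i + 2)
  for (k in list(c(2, 3, 1), c(4, 2, 2), c(1, 1, 3))) {
    neg <- c(idx(k[1], 4), idx(k[2], 4), idx(k[3], 4))
    expect_equal(d[k[1], k[2], k[3]], Conj(d[neg[1], neg[2], neg[3]]),
                 tolerance = 1e-6)
  }
  back <- fftImage(f)
  expect_equal(imageDomain(back), "spatial")
  expect_false(is.complex(imageData(back)))
  expect_equal(imageData(back), imageData(x), tolerance = 1e-9)

  # a non-symmetric frequency buffer transforms to a complex spatial image
  nf <- imageHandle(d + 0.5i, domain = "frequency",
                    conjugateSymmetric = FALSE)
  bs <- fftImage(nf)
  expect_equal(imageDomain(bs), "spatial")
  expect_true(is.complex(imageData(bs)))
})

test_that("a delta function transforms to a flat unit-magnitude spectrum", {
  d <- array(0, c(8, 8, 8)); d[1, 1, 1] <- 1
  f <- fftImage(imageHandle(d))
  expect_equal(Mod(imageData(f)), array(1, c(8, 8, 8)), tolerance = 1e-12)
})

test_that("the FFT agrees with a direct DFT and satisfies Parseval", {
  x <- randomMap(c(5, 4, 3), 72)
  f <- fftImage(x)
  expect_equal(imageData(f), naiveDFT3(imageData(x)), tolerance = 1e-8)
  expect_equal(sum(imageData(x)^2),
               sum(Mod(imageData(f))^2) / length(imageData(x)),
               tolerance = 1e-9)
})

test_that("blur preserves DC and reproduces the sampled Gaussian", {
  flat <- imageHandle(array(2.5, c(8, 8, 8)))
  b <- gaussianBlur(flat, 1.5)
  expect_equal(imageData(b), imageData(flat), tolerance = 1e-12)

  d <- array(0, c(32, 32, 32)); d[17, 17, 17] <- 1
  img <- imageHandle(d, sampling = 1)
  b <- gaussianBlur(img, 2)
  expect_equal(mean(imageData(b)), mean(d), tolerance = 1e-12)
  co <- (1:32) - 17
  g <- exp(-co^2 / (2 * 2^2))
  expected <- (g %o% g %o% g) / (2 * pi * 2^2)^(3 / 2)
  expect_lt(max(abs(imageData(b) - expected)), 1e-6)
  expect_error(gaussianBlur(img, 0), "sigma")
})

test_that("low- and high-pass filters split the spectrum", {
  x <- randomMap(c(12, 12, 12), 73)
  lp <- lowPass(x, 4)
  hp <- highPass(lp, 4)
  # complementary supports: only the |k| == 1/cutoff shell survives
  k2 <- molkit:::.freqSq(c(12, 12, 12), rep(1, 3))
  shell <- sum(abs(k2 - 1 / 16) < 1e-12)
  offShell <- abs(k2 - 1 / 16) >= 1e-12
  spec <- imageData(fftImage(hp))
  expect_lt(max(Mod(spec[offShell])), 1e-9)
  # low + high (exclusive split would lose the shell; ours keeps it in both)
  both <- imageData(lowPass(x, 4)) + imageData(highPass(x, 4))
  residual <- both - imageData(x)
  spec2 <- imageData(fftImage(imageHandle(residual)))
  expect_lt(max(Mod(spec2[offShell])), 1e-8)
  expect_error(lowPass(x, 0), "cutoff")
})

test_that("masking multiplies voxelwise", {
  x <- randomMap(c(6, 6, 6), 74)
  m <- array(0, c(6, 6, 6)); m[1:3, , ] <- 1
  y <- applyMask(x, m)
  expect_equal(imageData(y), imageData(x) * m)
  expect_error(applyMask(x, array(1, c(2, 2, 2))), "dimensions")
})

singleAtomEntity <- function(pos) {
  createEntity(data.frame(chain = "A", resname = "UNL", resnum = 1,
    name = "C1", element = "C", x = pos[1], y = pos[2], z = pos[3]))
}

test_that("single-atom density follows the Gaussian closed form", {
  ent <- singleAtomEntity(c(0, 0, 0))
  par <- densityParams(sigma = 1, sampling = 0.5, padding = 3)
  m <- entityToDensity(asView(ent), par)
  co <- lapply(1:3, function(i)
    imageOrigin(m)[i] + (seq_len(dim(imageData(m))[i]) - 1) * 0.5)
  i0 <- vapply(co, function(v) which.min(abs(v)), integer(1))
  expect_equal(imageData(m)[i0[1], i0[2], i0[3]], 1, tolerance = 1e-12)
  off <- which.min(abs(co[[1]] - 1))   # 1 Angstrom along x
  expect_equal(imageData(m)[off, i0[2], i0[3]], exp(-0.5), tolerance = 1e-6)
  expect_error(entityToDensity(createView(ent, integer())), "empty")
})

test_that("density is additive and matches the exhaustive double loop", {
  a <- singleAtomEntity(c(0, 0, 0))
  par <- densityParams(sigma = 1.2, sampling = 1, padding = 4)
  grid <- entityToDensity(asView(a), par)

  both <- createEntity(data.frame(chain = "A", resname = "UNL", resnum = 1,
    name = c("C1", "C2"), element = "C",
    x = c(-1, 1.5), y = c(0.5, -0.5), z = c(0, 1)))
  m2 <- entityToDensity(asView(both), par, grid = grid)
  mA <- entityToDensity(createView(both, 1L), par, grid = grid)
  mB <- entityToDensity(createView(both, 2L), par, grid = grid)
  expect_equal(imageData(m2), imageData(mA) + imageData(mB),
               tolerance = 1e-12)

  set.seed(75)
  frag <- makePointCloud(10, seed = 75, box = 6)
  fm <- entityToDensity(asView(frag), par)
  naive <- naiveDensity(positions(frag), rep(1, 10), dim(imageData(fm)),
                        imageSampling(fm), imageOrigin(fm), 1.2)
  expect_lt(max(abs(imageData(fm) - naive)) / max(naive), 1e-4)
})

test_that("density generation is translation-equivariant", {
  frag <- makePointCloud(6, seed = 76, box = 5)
  par <- densityParams(sigma = 1.5, sampling = 1)
  m1 <- entityToDensity(asView(frag), par)
  delta <- c(3.2, -1.1, 0.7)
  setPositions(frag, sweep(positions(frag), 2, -delta))
  m2 <- entityToDensity(asView(frag), par)
  expect_equal(imageData(m2), imageData(m1), tolerance = 1e-12)
  expect_equal(imageOrigin(m2), imageOrigin(m1) + delta)
})

test_that("real-space correlation behaves like a Pearson coefficient", {
  m <- entityToDensity(asView(makePointCloud(8, seed = 77, box = 5)))
  expect_equal(realSpaceCorrelation(m, m), 1.0)
  neg <- imageHandle(-imageData(m), imageSampling(m), imageOrigin(m))
  expect_equal(realSpaceCorrelation(m, neg), -1.0)

  noisy <- imageHandle(imageData(m) + rnorm(length(imageData(m)), sd = 0.05),
                       imageSampling(m), imageOrigin(m))
  a <- as.numeric(imageData(m)); b <- as.numeric(imageData(noisy))
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(realSpaceCorrelation(m, noisy), direct, tolerance = 1e-12)

  # affine rescaling invariance
  resc <- imageHandle(3.7 * imageData(noisy) + 11,
                      imageSampling(m), imageOrigin(m))
  expect_equal(realSpaceCorrelation(m, resc),
               realSpaceCorrelation(m, noisy), tolerance = 1e-12)

  flat <- imageHandle(array(1, dim(imageData(m))), imageSampling(m),
                      imageOrigin(m))
  expect_error(realSpaceCorrelation(m, flat), "zero-variance")
})

test_that("fragment scoring ranks the true fragment first at SNR >= 2", {
  set.seed(78)
  true <- makePolyalaHelix(6)
  par <- densityParams(sigma = 1.5, sampling = 1)
  expMapClean <- entityToDensity(asView(true), par)
  # SNR 2: noise sd = half the map's signal sd
  snr <- 2
  noise <- rnorm(length(imageData(expMapClean)),
                 sd = sd(as.numeric(imageData(expMapClean))) / snr)
  expMap <- imageHandle(imageData(expMapClean) + noise,
                        imageSampling(expMapClean), imageOrigin(expMapClean))

  decoys <- lapply(c(3, 4.5, 6), function(d) {
    e <- makePolyalaHelix(6)
    applyTransform(e, diag(3), c(d, 0, 0))
    asView(e)
  })
  frags <- c(list(asView(true)), decoys)
  sc <- scoreFragments(frags, expMap, par)
  expect_equal(sc$fragment[1], 1)
  expect_true(all(sc$correlation[-1] < sc$correlation[1]))

  # noise-free self-map: correlation 1 at the top
  sc0 <- scoreFragments(list(asView(true)), expMapClean, par)
  expect_equal(sc0$correlation, 1.0, tolerance = 1e-9)

  # composition: the score equals the two underlying operations
  fmap <- entityToDensity(decoys[[1]], par, grid = expMap)
  mask <- molkit:::.footprintMask(decoys[[1]], expMap, 4 * par$sigma)
  expect_equal(sc$correlation[sc$fragment == 2],
               realSpaceCorrelation(fmap, expMap, region = mask))
})

test_that("MRC round trips preserve grid metadata and voxel values", {
  m <- randomMap(c(8, 7, 6), 79)
  m <- imageHandle(imageData(m), sampling = 1.5, origin = c(1, -2, 3.5))
  f <- tempfile(fileext = ".mrc")
  writeMRC(m, f)
  r1 <- readMRC(f)
  expect_equal(dim(imageData(r1)), c(8, 7, 6))
  expect_equal(imageSampling(r1), rep(1.5, 3))
  expect_equal(imageOrigin(r1), c(1, -2, 3.5))
  expect_equal(imageData(r1), imageData(m), tolerance = 1e-6)
  # float32 storage is exact from the second trip on
  f2 <- tempfile(fileext = ".mrc")
  writeMRC(r1, f2)
  r2 <- readMRC(f2)
  expect_identical(imageData(r2), imageData(r1))
})

test_that("axis-permuted MRC headers are unscrambled to x,y,z order", {
  arr <- array(seq_len(4 * 3 * 2), c(4, 3, 2))   # canonical truth
  # store with MAPC/MAPR/MAPS = 2,1,3: disk fast axis = canonical y
  disk <- aperm(arr, c(2, 1, 3))                 # dims 3,4,2
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  wI <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wF <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wI(dim(disk)); wI(2L)            # nx ny nz (disk order), mode
  wI(c(0L, 0L, 0L))                # nstart
  wI(c(4L, 3L, 2L))                # mx my mz (canonical grid)
  wF(c(4, 3, 2) * 1.0)             # cell: sampling 1
  wF(c(90, 90, 90))
  wI(c(2L, 1L, 3L))                # mapc mapr maps
  wF(c(min(disk), max(disk), mean(disk)))
  wI(c(1L, 0L)); writeBin(raw(100), con)
  wF(c(0, 0, 0)); writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wF(sd(as.numeric(disk))); wI(0L)
  writeBin(raw(800), con)
  writeBin(as.double(as.numeric(disk)), con, size = 4, endian = "little")
  close(con)
  r <- readMRC(f)
  expect_equal(dim(imageData(r)), c(4, 3, 2))
  expect_equal(imageData(r), arr, ignore_attr = TRUE)
})
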