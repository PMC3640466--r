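# PDB fixed-column I/O under profiles; DCD in-memory and lazy reading.

pdbLine <- function(x = 1.0, y = 2.0, z = 3.0, xs = NULL) {
  sprintf("ATOM      1  CA  ALA A   1    %s%8.3f%8.3f  1.00 10.00           C",
          if (is.null(xs)) sprintf("%8.3f", x) else xs, y, z)
}

test_that("well-formed ATOM records parse at their fixed columns", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(pdbLine(), "END"), f)
  e <- readPDB(f)
  expect_equal(atomCount(e), 1)
  a <- atoms(e)
  expect_equal(a$name, "CA")
  expect_equal(a$resname, "ALA")
  expect_equal(a$chain, "A")
  expect_equal(a$resnum, 1L)
  expect_equal(as.numeric(positions(e)), c(1, 2, 3))
  expect_equal(a$occ, 1.0)
  expect_equal(a$bfac, 10.0)
  expect_false(a$ishetatm)
})

test_that("malformed records abort under strict and skip when tolerant", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(pdbLine(), pdbLine(xs = "   abc  "), "END"), f)
  expect_error(readPDB(f, ioProfile()), "line 2")
  tol <- ioProfile(strict = FALSE, faultTolerant = TRUE,
                   processConnectivity = "none")
  e <- readPDB(f, tol)
  expect_equal(atomCount(e), 1)
  expect_true(any(grepl("line 2", ioDiagnostics(e))))
})

test_that("alt-locs resolve to highest occupancy, ties to lowest letter", {
  l1 <- "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C"
  l2 <- "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C"
  l3 <- "ATOM      3  CB BALA A   1       4.000   0.000   0.000  0.50 10.00           C"
  l4 <- "ATOM      4  CB AALA A   1       3.000   0.000   0.000  0.50 10.00           C"
  f <- tempfile(fileext = ".pdb")
  writeLines(c(l1, l2, l3, l4, "END"), f)
  e <- readPDB(f, ioProfile(processConnectivity = "none"))
  expect_equal(atomCount(e), 2)
  p <- positions(e)
  expect_equal(p[atoms(e)$name == "CA", 1], 2)  # higher occupancy wins
  expect_equal(p[atoms(e)$name == "CB", 1], 3)  # tie: altloc A wins
})

test_that("only the first MODEL is imported and HETATMs obey the profile", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", pdbLine(), "ENDMDL", "MODEL        2",
    sub("^ATOM      1", "ATOM      9", pdbLine(x = 9)), "ENDMDL", "END"), f)
  e <- readPDB(f, ioProfile(processConnectivity = "none"))
  expect_equal(atomCount(e), 1)
  expect_equal(positions(e)[1, 1], 1)

  f2 <- tempfile(fileext = ".pdb")
  het <- sprintf(
    "HETATM    2  O   HOH A   2    %8.3f%8.3f%8.3f  1.00  0.00           O",
    5, 0, 0)
  writeLines(c(pdbLine(), het, "END"), f2)
  both <- readPDB(f2, ioProfile(processConnectivity = "none"))
  expect_equal(atomCount(both), 2)
  noHet <- readPDB(f2, ioProfile(processConnectivity = "none",
                                 readHetatms = FALSE))
  expect_equal(atomCount(noHet), 1)
})

test_that("write/read round trips preserve the atom table", {
  h <- makePolyalaHelix(4)
  f <- tempfile(fileext = ".pdb")
  writePDB(h, f)
  e <- readPDB(f)   # strict default profile accepts our own output
  expect_equal(atomCount(e), atomCount(h))
  expect_identical(atoms(e)$name, atoms(h)$name)
  expect_identical(atoms(e)$resnum, atoms(h)$resnum)
  expect_equal(positions(e), round(positions(h), 3), tolerance = 1e-12)

  cloud <- makePointCloud(60, seed = 2)
  f2 <- tempfile(fileext = ".pdb")
  writePDB(cloud, f2)
  e2 <- readPDB(f2, ioProfile(processConnectivity = "none"))
  expect_equal(atomCount(e2), 60)
  expect_identical(atoms(e2)$element, atoms(cloud)$element)
  expect_equal(atoms(e2)$charge, atoms(cloud)$charge)
  expect_equal(atoms(e2)$occ, atoms(cloud)$occ)

  # a view writes exactly its own atoms
  v <- select(h, "aname=CA")
  f3 <- tempfile(fileext = ".pdb")
  writePDB(v, f3)
  e3 <- readPDB(f3, ioProfile(processConnectivity = "none"))
  expect_equal(atomCount(e3), 4)
  expect_setequal(atoms(e3)$name, "CA")

  long <- createEntity(data.frame(chain = "A", resname = "ABCDE",
    resnum = 1, name = "C1", element = "C", x = 0, y = 0, z = 0))
  expect_error(writePDB(long, tempfile()), "3-character")
  far <- createEntity(data.frame(chain = "A", resname = "UNL",
    resnum = 1, name = "C1", element = "C", x = 12345.0, y = 0, z = 0))
  expect_error(writePDB(far, tempfile()), "overflow")
})

test_that("our PDB output agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  h <- makePolyalaHelix(5)
  f <- tempfile(fileext = ".pdb")
  writePDB(h, f)
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ref$atom), atomCount(h))
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE),
               round(positions(h), 3), ignore_attr = TRUE)
  expect_identical(ref$atom$elety, atoms(h)$name)
})

test_that("DCD striding, mode equivalence and fixture round trip", {
  h <- makePolyalaHelix(5)
  f <- tempfile(fileext = ".dcd")
  cent <- makeTrajectory(h, f, nFrames = 10, motion = "sinusoid",
                         amplitude = 1, period = 10)
  t2 <- readDCD(f, h, stride = 2)
  expect_equal(frameCount(t2), 5)

  tm <- readDCD(f, h, mode = "in_memory")
  tl <- readDCD(f, h, mode = "lazy", cacheSize = 4)
  expect_equal(frameCount(tm), 10)
  for (i in c(3, 1, 10, 3))
    expect_identical(framePositions(tm, i), framePositions(tl, i))

  # analytic centroid of the sinusoid fixture (float32 storage)
  for (i in 1:10)
    expect_equal(colMeans(framePositions(tm, i)), cent[i, ],
                 tolerance = 1e-5, ignore_attr = TRUE)

  # unit-cell block is honoured and skipped
  fc <- tempfile(fileext = ".dcd")
  writeDCD(lapply(1:3, function(i) positions(h) + i), fc,
           cell = c(50, 90, 50, 90, 90, 50))
  tc <- readDCD(fc, h)
  expect_equal(framePositions(tc, 2), positions(h) + 2, tolerance = 1e-5)
})

test_that("lazy trajectories bound their cache and count fetches", {
  h <- makePolyalaHelix(4)
  f <- tempfile(fileext = ".dcd")
  makeTrajectory(h, f, nFrames = 20, motion = "brownian", seed = 8)
  tl <- readDCD(f, h, mode = "lazy", cacheSize = 3)
  expect_equal(fetchCount(tl), 0)
  for (i in 1:10) framePositions(tl, i)
  expect_equal(fetchCount(tl), 10)
  expect_lte(residentFrames(tl), 3)
  # cached frames are served without a new fetch
  framePositions(tl, 10)
  expect_equal(fetchCount(tl), 10)
  # and the LRU really evicted the oldest
  framePositions(tl, 1)
  expect_equal(fetchCount(tl), 11)
})

test_that("DCD errors: magic, atom count, truncation, index range", {
  h <- makePolyalaHelix(4)
  f <- tempfile(fileext = ".dcd")
  makeTrajectory(h, f, nFrames = 3)
  expect_error(readDCD(f, makePolyalaHelix(5)), "atom count")

  bad <- tempfile(fileext = ".dcd")
  writeBin(as.integer(c(84, 1, 2)), bad, size = 4)
  expect_error(readDCD(bad, h), "magic")

  tr <- readDCD(f, h)
  expect_error(framePositions(tr, 0), "out of range")
  expect_error(framePositions(tr, 4), "out of range")

  # truncate the last frame and try to read it lazily
  sz <- file.size(f)
  trunc <- tempfile(fileext = ".dcd")
  raw <- readBin(f, "raw", sz - 10)
  writeBin(raw, trunc)
  tl <- readDCD(trunc, h, mode = "lazy")
  expect_equal(frameCount(tl), 2)  # incomplete frame not counted
})

test_that("our DCD writer is readable by an independent reader", {
  skip_if_not_installed("bio3d")
  h <- makePolyalaHelix(4)
  f <- tempfile(fileext = ".dcd")
  makeTrajectory(h, f, nFrames = 6, motion = "sinusoid")
  ref <- suppressWarnings(bio3d::read.dcd(f, verbose = FALSE))
  tm <- readDCD(f, h)
  expect_equal(nrow(ref), 6)
  for (i in 1:6)
    expect_equal(matrix(ref[i, ], ncol = 3, byrow = TRUE),
                 framePositions(tm, i), ignore_attr = TRUE,
                 tolerance = 1e-6)
})

test_that("applyFrame moves the entity and its views", {
  h <- makePolyalaHelix(3)
  v <- select(h, "aname=CA")
  f <- tempfile(fileext = ".dcd")
  makeTrajectory(h, f, nFrames = 5, motion = "sinusoid", amplitude = 3,
                 period = 4)
  tr <- readDCD(f, h)
  p0 <- positions(v)
  applyFrame(tr, 2)   # sin(2*pi/4) = 1 -> shift +3 in x
  expect_equal(positions(v)[, 1], p0[, 1] + 3, tolerance = 1e-5)
  got <- findWithin(v, positions(v)[1, ], 0.01)
  expect_identical(got, v@atomIds[1])
})
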