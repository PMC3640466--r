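# Kabsch superposition, RMSD, annotation transfer.

randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

cloudEntity <- function(n, seed) {
  set.seed(seed)
  createEntity(data.frame(chain = "A", resname = "UNL", resnum = 1,
    name = paste0("X", 1:n), element = "C",
    x = rnorm(n, sd = 4), y = rnorm(n, sd = 4), z = rnorm(n, sd = 4)))
}

test_that("identical coordinate sets superpose to the identity", {
  a <- makePolyalaHelix(5); b <- makePolyalaHelix(5)
  r <- superpose(asView(a), asView(b))
  expect_lt(r@rmsd, 1e-9)
  expect_equal(r@rotation, diag(3), tolerance = 1e-9)
  expect_equal(r@translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(r@atomCount, 25L)
})

test_that("constructed rigid transforms are recovered exactly", {
  ref <- cloudEntity(12, 21)
  mob <- cloudEntity(12, 21)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  applyTransform(mob, R, c(1, 2, 3))
  r <- superpose(asView(mob), asView(ref), apply = TRUE)
  expect_lt(r@rmsd, 1e-6)
  expect_equal(r@rotation %*% R, diag(3), tolerance = 1e-9)
  expect_equal(det(r@rotation), 1, tolerance = 1e-12)
  # apply = TRUE moved the mobile handle onto the reference
  expect_lt(rmsd(asView(mob), asView(ref)), 1e-9)
})

test_that("no random proper rotation improves on the Kabsch optimum", {
  set.seed(22)
  for (k in 1:5) {
    a <- cloudEntity(10, 300 + k)
    b <- cloudEntity(10, 400 + k)
    r <- superpose(asView(a), asView(b))
    # reported rmsd equals direct evaluation of the returned transform
    expect_equal(r@rmsd, rmsd(asView(a), asView(b), r@rotation,
                              r@translation), tolerance = 1e-12)
    P <- positions(a); Q <- positions(b)
    for (m in 1:200) {
      Rr <- randomRotation()
      moved <- sweep(sweep(P, 2, colMeans(P)) %*% t(Rr), 2,
                     -colMeans(Q))
      expect_gte(sqrt(mean(rowSums((moved - Q)^2))), r@rmsd - 1e-9)
    }
  }
})

test_that("superposition is symmetric and rigid-invariant", {
  a <- cloudEntity(15, 31); b <- cloudEntity(15, 32)
  r1 <- superpose(asView(a), asView(b))@rmsd
  r2 <- superpose(asView(b), asView(a))@rmsd
  expect_equal(r1, r2, tolerance = 1e-9)

  Rr <- {set.seed(33); randomRotation()}
  applyTransform(a, Rr, c(5, -2, 1))
  applyTransform(b, Rr, c(5, -2, 1))
  expect_equal(superpose(asView(a), asView(b))@rmsd, r1, tolerance = 1e-9)
})

test_that("degenerate and mismatched inputs are rejected or flagged", {
  a <- cloudEntity(5, 41); b <- cloudEntity(6, 42)
  expect_error(superpose(asView(a), asView(b)), "mismatch")
  two <- cloudEntity(2, 43)
  expect_error(superpose(asView(two), asView(two)), "at least 3")
  line <- createEntity(data.frame(chain = "A", resname = "UNL", resnum = 1,
    name = paste0("X", 1:4), element = "C", x = 1:4, y = 0, z = 0))
  expect_warning(superpose(asView(line), asView(line)), "degenerate")
})

test_that("the same routine superposes any equally sized selections", {
  a <- makePolyalaHelix(8); b <- makePolyalaHelix(8)
  applyTransform(b, randomRotation(), c(3, 1, -2))
  rCA <- superpose(select(b, "aname=CA"), select(a, "aname=CA"))
  rCB <- superpose(select(b, "aname=CB"), select(a, "aname=CB"))
  expect_lt(rCA@rmsd, 1e-6)
  expect_lt(rCB@rmsd, 1e-6)
})

test_that("rmsd matches its closed forms and definition", {
  a <- cloudEntity(1, 51)
  b <- cloudEntity(1, 51)
  setPositions(b, positions(b) + c(3, 0, 0))
  expect_equal(rmsd(asView(a), asView(b)), 3)

  x <- cloudEntity(20, 52); y <- cloudEntity(20, 53)
  expect_equal(rmsd(asView(x), asView(y)),
               sqrt(mean(rowSums((positions(x) - positions(y))^2))))
  expect_error(rmsd(asView(x), asView(cloudEntity(5, 54))), "mismatch")
})

attachedPair <- function(srcStr, dstStr, alnSrc, alnDst) {
  ns <- nchar(gsub("-", "", alnSrc))
  nd <- nchar(gsub("-", "", alnDst))
  src <- makePolyalaHelix(ns); ruleBasedProcess(src)
  dst <- makePolyalaHelix(nd); ruleBasedProcess(dst)
  s1 <- attachView(createSequence("src", alnSrc), asView(src))
  s2 <- attachView(createSequence("dst", alnDst), asView(dst))
  list(src = s1, dst = s2,
       aln = createAlignment(s1, s2), srcEnt = src, dstEnt = dst)
}

test_that("annotation transfer follows the alignment mapping", {
  # poly-ALA helices: one-letter codes are all A, so any mapping is valid
  p <- attachedPair(alnSrc = "AAAAA", alnDst = "AAAAA")
  n <- transferAnnotation(p$src, p$dst, p$aln, "rnum=1:3", "site")
  expect_equal(n, 3)
  marked <- select(p$dstEnt, "gr:site=true")
  expect_equal(sort(unique(atoms(marked)$resnum)), 1:3)

  # a gap opposite one selected residue drops exactly that residue
  p2 <- attachedPair(alnSrc = "AAAAA", alnDst = "AA-AA")
  n2 <- transferAnnotation(p2$src, p2$dst, p2$aln, "rnum=1:3", "site")
  expect_equal(n2, 2)
  marked2 <- select(p2$dstEnt, "gr:site=true")
  expect_equal(sort(unique(atoms(marked2)$resnum)), 1:2)

  expect_error(transferAnnotation(p$src, p2$dst, p$aln, "rnum=1", "x"),
               "members of the alignment")
})

test_that("transferred index pairs equal the mapping-oracle composition", {
  set.seed(61)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    # random gapped renderings of two equal-length helices
    mkGapped <- function(n, L) {
      slots <- sort(sample(L, n))
      s <- rep("-", L); s[slots] <- "A"
      paste(s, collapse = "")
    }
    L <- n + sample(2:4, 1)
    aS <- mkGapped(n, L); aD <- mkGapped(n, L)
    p <- attachedPair(alnSrc = aS, alnDst = aD)
    sel <- sample(n, sample(n, 1))
    q <- paste0("rnum=", paste(sel, collapse = ","))
    got <- transferAnnotation(p$src, p$dst, p$aln, q, "site")
    # oracle: char positions of src residues, read dst at those columns
    cs <- strsplit(aS, "")[[1]]; cd <- strsplit(aD, "")[[1]]
    srcCols <- which(cs != "-")[sel]
    expect_equal(got, sum(cd[srcCols] != "-"))
    dstIdx <- cumsum(cd != "-")[srcCols][cd[srcCols] != "-"]
    markedRes <- sort(unique(atoms(select(p$dstEnt, "gr:site=true"))$resnum))
    expect_equal(markedRes, sort(unique(dstIdx)))
  }
})
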