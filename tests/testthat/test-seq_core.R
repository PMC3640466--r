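# Gapped sequences, gap-list mapping, structure attachment, alignment
# editing, sequence file formats.

randomGapped <- function(len) {
  paste(sample(c(LETTERS[1:6], "-", "-"), len, replace = TRUE),
        collapse = "")
}

test_that("gap lists reconstruct the gap structure of the string", {
  s <- createSequence("s", "AB--C")
  expect_equal(unname(gapList(s)[, "start"]), 3)
  expect_equal(unname(gapList(s)[, "length"]), 2)

  s2 <- createSequence("s", "-A-A-")
  expect_equal(unname(gapList(s2)[, "start"]), c(1, 3, 5))
  expect_equal(unname(gapList(s2)[, "length"]), c(1, 1, 1))

  expect_error(createSequence("s", "AB?C"), "illegal")
  # '.' normalised, case folded
  s3 <- createSequence("s", "a.b")
  expect_equal(sequenceString(s3), "A-B")
})

test_that("position/index mapping matches the naive scan everywhere", {
  s <- createSequence("s", "AB--C")
  expect_equal(posToResidueIndex(s, 5), 3)
  expect_true(is.na(posToResidueIndex(s, 3)))
  expect_equal(residueIndexToPos(s, 3), 5)
  expect_error(posToResidueIndex(s, 6), "out of range")
  expect_error(residueIndexToPos(s, 4), "out of range")
  expect_error(residueIndexToPos(s, 0), "out of range")

  ung <- createSequence("s", "ABCDEF", offset = 10L)
  for (p in 1:6) expect_equal(posToResidueIndex(ung, p), p + 10)

  set.seed(5)
  for (k in 1:200) {
    str <- randomGapped(sample(5:60, 1))
    s <- createSequence("r", str)
    ch <- strsplit(str, "")[[1]]
    for (pos in seq_along(ch)) {
      got <- posToResidueIndex(s, pos)
      if (ch[pos] == "-") expect_true(is.na(got))
      else {
        expect_equal(got, pos - naiveGapsBefore(str, pos))
        expect_equal(residueIndexToPos(s, got), pos)
      }
    }
  }
})

test_that("mapping inspects at most gap-run-count gap-list entries", {
  set.seed(6)
  for (k in 1:50) {
    str <- randomGapped(sample(10:80, 1))
    s <- createSequence("r", str)
    runs <- nrow(gapList(s))
    for (pos in sample(nchar(str), min(10, nchar(str)))) {
      r <- posToResidueIndex(s, pos, counted = TRUE)
      expect_lte(r$inspected, max(runs, 1))
    }
    ng <- nonGapCount(s)
    if (ng > 0) {
      r <- residueIndexToPos(s, ng, counted = TRUE)
      expect_lte(r$inspected, max(runs, 1))
    }
  }
})

attachedHelix <- function(n, seqStr) {
  h <- makePolyalaHelix(n)
  ruleBasedProcess(h)
  attachView(createSequence("s", seqStr), asView(h))
}

test_that("structure attachment validates and resolves positions", {
  s <- attachedHelix(3, "AAA")
  expect_false(is.null(attachedView(s)))
  r <- residueAtPos(s, 2)
  expect_equal(r$resnum, 2)

  expect_error(attachedHelix(3, "AVA"), "position 2")
  expect_error(attachedHelix(4, "AAA"), "non-gap")
  # X wildcard matches anything
  expect_s4_class(attachedHelix(3, "AXA"), "SequenceHandle")

  g <- attachedHelix(3, "A-AA")
  expect_null(residueAtPos(g, 2))
  expect_equal(residueAtPos(g, 3)$resnum, 2)
})

test_that("column editing keeps lengths equal and gap lists consistent", {
  aln <- createAlignment(a = "ABC", b = "A-C")
  a2 <- insertGapColumn(aln, 1)
  expect_identical(vapply(sequences(a2), sequenceString, ""),
                   c("-ABC", "-A-C"))
  back <- removeColumn(a2, 1)
  expect_identical(vapply(sequences(back), sequenceString, ""),
                   c("ABC", "A-C"))

  expect_error(removeColumn(aln, 2), "contains residues")
  forced <- removeColumn(aln, 2, force = TRUE)
  expect_equal(alignmentLength(forced), 2)
  expect_identical(alignmentColumn(aln, 2), c("B", "-"))

  # 50 random edits: gap lists still reconstruct their strings
  set.seed(9)
  cur <- createAlignment(a = "AB-CD-E", b = "-BBCDEE", c = "ABC--EE")
  for (k in 1:50) {
    L <- alignmentLength(cur)
    cur <- if (runif(1) < 0.5 || L < 3) insertGapColumn(cur, sample(L + 1, 1))
           else removeColumn(cur, sample(L, 1), force = TRUE)
    for (s in sequences(cur)) {
      ch <- strsplit(sequenceString(s), "")[[1]]
      rebuilt <- rep(FALSE, length(ch))
      gl <- gapList(s)
      for (r in seq_len(nrow(gl)))
        rebuilt[gl[r, 1] + seq_len(gl[r, 2]) - 1] <- TRUE
      expect_identical(rebuilt, ch == "-")
    }
  }
})

test_that("FASTA round trips preserve names and strings", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "ACDEFG", ">seq2 a description", "HIKL-M"), f)
  sl <- readSequences(f)
  expect_length(sequences(sl), 2)
  expect_equal(sequenceName(sequences(sl)[[1]]), "seq1")
  expect_equal(sequenceString(sequences(sl)[[2]]), "HIKL-M")

  f2 <- tempfile(fileext = ".fasta")
  writeFasta(sl, f2)
  back <- readSequences(f2)
  expect_identical(vapply(sequences(back), sequenceString, ""),
                   vapply(sequences(sl), sequenceString, ""))
  expect_identical(vapply(sequences(back), sequenceName, ""),
                   c("seq1", "seq2"))

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">a", "ACE"), dup)
  expect_error(readSequences(dup), "duplicate")
})

test_that("ClustalW blocks concatenate to the FASTA rendering", {
  s1 <- paste(rep("ACDEFGHIKLMN", 10), collapse = "")   # 120 columns
  s2 <- chartr("A", "C", s1)
  f <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               paste("one ", substr(s1, 1, 60)),
               paste("two ", substr(s2, 1, 60)), "",
               paste("one ", substr(s1, 61, 120)),
               paste("two ", substr(s2, 61, 120))), f)
  aln <- readAlignment(f)
  expect_equal(alignmentLength(aln), 120)
  ff <- tempfile(fileext = ".fasta")
  writeFasta(aln, ff)
  viaFasta <- readAlignment(ff, format = "fasta")
  expect_identical(vapply(sequences(aln), sequenceString, ""),
                   vapply(sequences(viaFasta), sequenceString, ""))

  ragged <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W", "", "one ACDE", "two ACD"), ragged)
  expect_error(readAlignment(ragged), "ragged|equal length")
})

test_that("PIR round trips preserve the header type", {
  f <- tempfile(fileext = ".pir")
  writeLines(c(">P1;prot1", "a protein", "ACDEF", "GHIK*",
               ">F1;frag1", "a fragment", "MNPQ*"), f)
  sl <- readSequences(f)
  expect_equal(sequenceString(sequences(sl)[[1]]), "ACDEFGHIK")
  expect_identical(pirTypes(f), c("P1", "F1"))

  f2 <- tempfile(fileext = ".pir")
  writePir(sl, f2, pirTypes = pirTypes(f))
  back <- readSequences(f2)
  expect_identical(vapply(sequences(back), sequenceString, ""),
                   vapply(sequences(sl), sequenceString, ""))
  expect_identical(pirTypes(f2), c("P1", "F1"))

  noStar <- tempfile(fileext = ".pir")
  writeLines(c(">P1;x", "desc", "ACDE"), noStar)
  expect_error(readSequences(noStar), "terminating")
})
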