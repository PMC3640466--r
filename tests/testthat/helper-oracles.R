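# Independent brute-force oracles.  Everything here recomputes expected
# values from first principles, sharing no code path with the package
# implementation it checks.

# exhaustive distance scan
bfWithin <- function(x, center, radius) {
  p <- positions(x)
  ids <- atoms(x)$id
  d <- sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
            (p[, 3] - center[3])^2)
  sort(ids[d <= radius + 1e-12])
}

# ---- query oracle: per-atom tuple filter -------------------------------

# materialize one atom's property tuple
.bfTuple <- function(tab, row) {
  a <- tab[row, ]
  list(aname = a$name, rname = a$resname, rnum = a$resnum, cname = a$chain,
       ele = a$element, occ = a$occ, abfac = a$bfac, ishetatm = a$ishetatm,
       charge = a$charge, id = a$id, resId = a$resId, chainId = a$chainId)
}

.bfCmp <- function(val, op, values) {
  if (is.logical(val)) {
    want <- vapply(values, function(v)
      (if (is.list(v)) v$str else v) %in% c("true", "1", "TRUE"), logical(1))
    hit <- any(val == want)
    return(if (op == "=") hit else !hit)
  }
  if (op %in% c("<", "<=", ">", ">=")) {
    v <- values[[1]]$num
    return(switch(op, "<" = val < v, "<=" = val <= v, ">" = val > v,
                  ">=" = val >= v))
  }
  hit <- FALSE
  for (v in values) {
    if (v$kind == "range") hit <- hit || (val >= v$lo && val <= v$hi)
    else if (is.numeric(val)) hit <- hit || (val == v$num)
    else hit <- hit || identical(val, v$str)
  }
  if (op == "=") hit else !hit
}

# evaluate one predicate for a single atom's property tuple
.bfPredAtom <- function(ent, ast, row, tab) {
  tup <- .bfTuple(tab, row)
  if (grepl("^g[arc]:", ast$prop)) {
    level <- switch(substr(ast$prop, 1, 2), ga = "atom", gr = "residue",
                    gc = "chain")
    id <- switch(level, atom = tup$id, residue = tup$resId,
                 chain = tup$chainId)
    key <- substr(ast$prop, 4, nchar(ast$prop))
    if (!hasProp(ent, key, level = level, id = id)) return(FALSE)
    .bfCmp(getProp(ent, key, level = level, id = id), ast$op, ast$values)
  } else .bfCmp(tup[[ast$prop]], ast$op, ast$values)
}

# naive filter: per-atom loop for predicates, each AST node evaluated once
bfEvalVec <- function(ent, ast, rows, tab = atoms(ent)) {
  switch(ast$kind,
    and = bfEvalVec(ent, ast$left, rows, tab) &
          bfEvalVec(ent, ast$right, rows, tab),
    or  = bfEvalVec(ent, ast$left, rows, tab) |
          bfEvalVec(ent, ast$right, rows, tab),
    not = !bfEvalVec(ent, ast$expr, rows, tab),
    within = {
      p <- positions(ent)
      refPos <- if (!is.null(ast$point)) matrix(ast$point, 1, 3)
      else p[rows[bfEvalVec(ent, ast$ref, rows, tab)], , drop = FALSE]
      vapply(rows, function(r) {
        if (!nrow(refPos)) return(FALSE)
        d2 <- (refPos[, 1] - p[r, 1])^2 + (refPos[, 2] - p[r, 2])^2 +
              (refPos[, 3] - p[r, 3])^2
        any(d2 <= ast$radius^2 + 1e-12)
      }, logical(1))
    },
    predicate = vapply(rows, function(r) .bfPredAtom(ent, ast, r, tab),
                       logical(1)),
    stop("bad ast"))
}

# full naive filter: atom ids of `ent` satisfying the AST
bfSelect <- function(ent, ast) {
  rows <- seq_len(atomCount(ent))
  sort(atoms(ent)$id[bfEvalVec(ent, ast, rows)])
}

# random query AST over the properties a point-cloud entity populates
randomAST <- function(ent, depth = 3) {
  a <- atoms(ent)
  mkPredicate <- function() {
    prop <- sample(c("aname", "rname", "rnum", "cname", "ele", "occ",
                     "abfac", "ishetatm", "charge"), 1)
    if (prop %in% c("rnum", "occ", "abfac", "charge")) {
      vals <- a[[c(rnum = "resnum", occ = "occ", abfac = "bfac",
                   charge = "charge")[[prop]]]]
      if (runif(1) < 0.3) {
        lo <- sample(vals, 1); hi <- sample(vals, 1)
        if (lo > hi) { t <- lo; lo <- hi; hi <- t }
        list(kind = "predicate", prop = prop, op = "=",
             values = list(list(kind = "range", lo = lo, hi = hi)))
      } else {
        op <- sample(c("=", "!=", "<", "<=", ">", ">="), 1)
        v <- sample(vals, 1)
        list(kind = "predicate", prop = prop, op = op,
             values = list(list(kind = "scalar", str = as.character(v),
                                num = as.numeric(v))))
      }
    } else if (prop == "ishetatm") {
      list(kind = "predicate", prop = prop, op = sample(c("=", "!="), 1),
           values = list(list(kind = "scalar",
                              str = sample(c("true", "false"), 1),
                              num = NA_real_)))
    } else {
      col <- c(aname = "name", rname = "resname", cname = "chain",
               ele = "element")[[prop]]
      k <- sample(1:2, 1)
      vs <- sample(unique(a[[col]]), min(k, length(unique(a[[col]]))))
      list(kind = "predicate", prop = prop, op = sample(c("=", "!="), 1),
           values = lapply(vs, function(v)
             list(kind = "scalar", str = v, num = NA_real_)))
    }
  }
  mk <- function(d) {
    if (d <= 0 || runif(1) < 0.4) return(mkPredicate())
    kind <- sample(c("and", "or", "not", "within"), 1,
                   prob = c(0.3, 0.3, 0.25, 0.15))
    switch(kind,
      and = list(kind = "and", left = mk(d - 1), right = mk(d - 1)),
      or = list(kind = "or", left = mk(d - 1), right = mk(d - 1)),
      not = list(kind = "not", expr = mk(d - 1)),
      within = list(kind = "within", radius = runif(1, 1, 8),
                    ref = mkPredicate()))
  }
  mk(depth)
}

# ---- alignment oracles: exhaustive enumeration -------------------------

# every global alignment, scored with affine gaps (gap run of length L
# costs open + (L-1) * extend); plain recursion over alignment columns
enumGlobal <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- scheme$matrix; go <- scheme$gapOpen; ge <- scheme$gapExtend
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, S[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    if (i <= n)
      best <- max(best, (if (last == "X") ge else go) + rec(i + 1, j, "X"))
    if (j <= m)
      best <- max(best, (if (last == "Y") ge else go) + rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "none")
}

# best local score: best-scoring path segment, any start, stop anywhere
enumLocal <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- scheme$matrix; go <- scheme$gapOpen; ge <- scheme$gapExtend
  suffix <- function(i, j, last) {
    best <- 0
    if (i <= n && j <= m)
      best <- max(best, S[A[i], B[j]] + suffix(i + 1, j + 1, "M"))
    if (i <= n && last != "none")
      best <- max(best, (if (last == "X") ge else go) + suffix(i + 1, j, "X"))
    if (j <= m && last != "none")
      best <- max(best, (if (last == "Y") ge else go) + suffix(i, j + 1, "Y"))
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, suffix(i, j, "none"))
  best
}

# ---- misc oracles ------------------------------------------------------

# gaps before an alignment position by naive character scan
naiveGapsBefore <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  sum(ch[seq_len(pos - 1)] == "-")
}

# conservation by explicit double loop over sequence pairs
naiveConservation <- function(strings, sim) {
  L <- nchar(strings[1])
  ns <- length(strings)
  chars <- lapply(strings, function(s) strsplit(s, "")[[1]])
  sapply(seq_len(L), function(c) {
    tot <- 0; np <- 0
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      a <- chars[[i]][c]; b <- chars[[j]][c]
      tot <- tot + if (a == "-" || b == "-") 0 else sim[a, b]
      np <- np + 1
    }
    tot / np
  })
}

# direct O(N^2) DFT of a 3-D array (forward, unscaled)
naiveDFT3 <- function(x) {
  d <- dim(x)
  out <- array(complex(real = 0), d)
  for (k1 in 0:(d[1] - 1)) for (k2 in 0:(d[2] - 1)) for (k3 in 0:(d[3] - 1)) {
    s <- 0 + 0i
    for (n1 in 0:(d[1] - 1)) for (n2 in 0:(d[2] - 1))
      for (n3 in 0:(d[3] - 1))
        s <- s + x[n1 + 1, n2 + 1, n3 + 1] *
          exp(-2i * pi * (k1 * n1 / d[1] + k2 * n2 / d[2] + k3 * n3 / d[3]))
    out[k1 + 1, k2 + 1, k3 + 1] <- s
  }
  out
}

# density without separability tricks or cutoff: all voxels x all atoms
naiveDensity <- function(pos, amp, dims, sampling, origin, sigma) {
  out <- array(0, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      v <- origin + (c(i, j, k) - 1) * sampling
      out[i, j, k] <- sum(amp * exp(-rowSums(sweep(pos, 2, v)^2) /
                                    (2 * sigma^2)))
    }
  out
}

expectSameAtomSet <- function(view, ids) {
  expect_identical(sort(view@atomIds), as.integer(ids))
}
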