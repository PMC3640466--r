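#' The selection query language
#'
#' Views are conveniently created with a small Boolean query language over
#' atom, residue and chain properties.  The grammar (EBNF):
#'
#' \preformatted{
#' query     = or_expr ;
#' or_expr   = and_expr , { "or" , and_expr } ;
#' and_expr  = not_expr , { "and" , not_expr } ;
#' not_expr  = "not" , not_expr | primary ;
#' primary   = "(" , or_expr , ")" | within | predicate ;
#' within    = number , "<>" ,
#'             ( "[" , or_expr , "]" | "{" , number , "," , number , "," , number , "}" ) ;
#' predicate = property , comp_op , value_list ;
#' property  = "aname" | "rname" | "rnum" | "cname" | "ele" | "occ"
#'           | "abfac" | "ishetatm" | "charge"
#'           | ( "ga:" | "gr:" | "gc:" ) , key ;
#' comp_op   = "=" | "!=" | "<" | "<=" | ">" | ">=" ;
#' value_list= value , { "," , value } ;
#' value     = token | number | number , ":" , number ;   (* colon = range *)
#' }
#'
#' Built-in properties: \code{aname} atom name, \code{rname} residue name,
#' \code{rnum} residue number, \code{cname} chain name, \code{ele}
#' element, \code{occ} occupancy, \code{abfac} isotropic B factor,
#' \code{ishetatm} HETATM flag (\code{true}/\code{false}), \code{charge}.
#' Comma lists are disjunctions (\code{aname=CA,CB}); colon ranges are
#' inclusive and only valid on numeric properties (\code{rnum=10:20}).
#' Relational operators \code{< <= > >=} require numeric properties;
#' string properties support \code{=}/\code{!=} only (case sensitive).
#' \code{not} binds tighter than \code{and}, which binds tighter than
#' \code{or}; parentheses group.
#'
#' Generic properties (see \code{\link{setProp}}) are addressed with a
#' level prefix: \code{ga:key} (atom), \code{gr:key} (residue),
#' \code{gc:key} (chain), e.g. \code{"gr:conservation>0.5"}.  Elements
#' lacking the key simply do not match.
#'
#' The proximity operator selects atoms within a radius (Angstrom) of any
#' atom matched by a sub-query, or of a literal point:
#' \code{"5 <> [rname=HEM]"}, \code{"4 <> {1.0,2.0,3.0}"}.  Matched atoms
#' are included as atoms only (no residue promotion).
#'
#' Because queries apply to handles and to views alike, selections chain:
#' \code{select(select(e, "cname=A"), "aname=CA")} equals
#' \code{select(e, "cname=A and aname=CA")}.
#'
#' @param x an \linkS4class{EntityHandle} or \linkS4class{EntityView}.
#' @param query query string.
#' @return \code{select} and \code{evaluateQuery} return an
#'   \linkS4class{EntityView}; \code{parseQuery} returns the abstract
#'   syntax tree (a nested list, invisibly printable).
#' @examples
#' ent <- makePolyalaHelix(5)
#' atomCount(select(ent, "aname=CA"))
#' atomCount(select(ent, "rnum=2:3 and aname=CA,CB"))
#' @name queryLanguage
NULL

.builtinProps <- c("aname", "rname", "rnum", "cname", "ele", "occ", "abfac",
                   "ishetatm", "charge")
.numericProps <- c("rnum", "occ", "abfac", "charge")

# ---- tokenizer ---------------------------------------------------------

.qTokenize <- function(text) {
  toks <- list()
  i <- 1L; n <- nchar(text)
  push <- function(type, lex, col) toks[[length(toks) + 1L]] <<-
    list(type = type, lex = lex, col = col)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(" ", "\t", "\n")) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (ch == "<" && substr(text, i + 1L, i + 1L) == ">") {
      push("op", "<>", i); i <- i + 2L; next
    }
    m <- regmatches(rest, regexpr("^(!=|<=|>=|=|<|>)", rest))
    if (length(m) && nzchar(m)) { push("op", m, i); i <- i + nchar(m); next }
    if (ch %in% c("(", ")", "[", "]", "{", "}", ",", ":")) {
      push("punct", ch, i); i <- i + 1L; next
    }
    m <- regmatches(rest, regexpr("^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
                                  rest))
    if (length(m) && nzchar(m)) {
      # a number immediately followed by identifier chars is a word (e.g. 1ABC)
      after <- substr(text, i + nchar(m), i + nchar(m))
      if (!grepl("^[A-Za-z_']$", after)) {
        push("num", m, i); i <- i + nchar(m); next
      }
    }
    m <- regmatches(rest, regexpr("^[A-Za-z0-9_'*][A-Za-z0-9_'*]*(:[A-Za-z0-9_.]+)?",
                                  rest))
    if (length(m) && nzchar(m)) {
      lex <- m
      # only the generic-property prefixes keep an embedded colon
      if (grepl(":", lex) && !grepl("^g[arc]:", lex)) {
        lex <- sub(":.*$", "", lex)
      }
      push("word", lex, i); i <- i + nchar(lex); next
    }
    stop(sprintf("query syntax error: unexpected character '%s' at column %d",
                 ch, i))
  }
  push("eof", "", n + 1L)
  toks
}

# ---- parser ------------------------------------------------------------

#' @rdname queryLanguage
#' @export
parseQuery <- function(query) {
  toks <- .qTokenize(query)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type, lex = NULL) {
    t <- peek()
    ok <- t$type == type && (is.null(lex) || t$lex == lex)
    if (!ok) stop(sprintf(
      "query syntax error at column %d: expected %s, found '%s'",
      t$col, if (is.null(lex)) type else paste0("'", lex, "'"), t$lex))
    advance()
  }
  fail <- function(msg, t = peek())
    stop(sprintf("query syntax error at column %d: %s", t$col, msg))

  parseOr <- function() {
    left <- parseAnd()
    while (peek()$type == "word" && peek()$lex == "or") {
      advance()
      left <- list(kind = "or", left = left, right = parseAnd())
    }
    left
  }
  parseAnd <- function() {
    left <- parseNot()
    while (peek()$type == "word" && peek()$lex == "and") {
      advance()
      left <- list(kind = "and", left = left, right = parseNot())
    }
    left
  }
  parseNot <- function() {
    if (peek()$type == "word" && peek()$lex == "not") {
      advance()
      return(list(kind = "not", expr = parseNot()))
    }
    parsePrimary()
  }
  parsePrimary <- function() {
    t <- peek()
    if (t$type == "punct" && t$lex == "(") {
      advance(); e <- parseOr(); expect("punct", ")"); return(e)
    }
    if (t$type == "num") return(parseWithin())
    if (t$type == "word") return(parsePredicate())
    fail(sprintf("expected a predicate, '(' or a within-expression, found '%s'",
                 if (t$type == "eof") "end of query" else t$lex), t)
  }
  parseWithin <- function() {
    t <- expect("num")
    radius <- as.numeric(t$lex)
    if (radius < 0) fail("within radius must be >= 0", t)
    expect("op", "<>")
    t2 <- peek()
    if (t2$type == "punct" && t2$lex == "[") {
      advance(); sub <- parseOr(); expect("punct", "]")
      return(list(kind = "within", radius = radius, ref = sub))
    }
    if (t2$type == "punct" && t2$lex == "{") {
      advance()
      xyz <- numeric(3)
      for (k in 1:3) {
        tn <- expect("num"); xyz[k] <- as.numeric(tn$lex)
        if (k < 3) expect("punct", ",")
      }
      expect("punct", "}")
      return(list(kind = "within", radius = radius, point = xyz))
    }
    fail("expected '[' or '{' after '<>'", t2)
  }
  parsePredicate <- function() {
    t <- expect("word")
    prop <- t$lex
    generic <- grepl("^g[arc]:.", prop)
    if (!generic && !prop %in% .builtinProps)
      fail(sprintf("unknown property name '%s'", prop), t)
    tOp <- peek()
    if (tOp$type != "op" || tOp$lex == "<>")
      fail(sprintf("expected a comparison operator after '%s'", prop), tOp)
    advance()
    op <- tOp$lex
    vals <- list(parseValue(op))
    while (peek()$type == "punct" && peek()$lex == ",") {
      advance(); vals[[length(vals) + 1L]] <- parseValue(op)
    }
    if (op %in% c("<", "<=", ">", ">=")) {
      if (length(vals) != 1L || vals[[1]]$kind != "scalar" ||
          is.na(vals[[1]]$num))
        fail(sprintf("operator '%s' takes a single numeric value", op), tOp)
    }
    list(kind = "predicate", prop = prop, op = op, values = vals,
         col = t$col)
  }
  parseValue <- function(op) {
    t <- peek()
    if (t$type == "num") {
      advance()
      lo <- as.numeric(t$lex)
      if (peek()$type == "punct" && peek()$lex == ":") {
        advance()
        t2 <- peek()
        if (t2$type != "num") fail("malformed range: expected a number", t2)
        advance()
        hi <- as.numeric(t2$lex)
        if (lo > hi) fail("malformed range: lower bound exceeds upper", t)
        return(list(kind = "range", lo = lo, hi = hi))
      }
      return(list(kind = "scalar", str = t$lex, num = lo))
    }
    if (t$type == "word" && !t$lex %in% c("and", "or", "not")) {
      advance()
      return(list(kind = "scalar", str = t$lex, num = NA_real_))
    }
    fail(sprintf("expected a value, found '%s'",
                 if (t$type == "eof") "end of query" else t$lex), t)
  }

  ast <- parseOr()
  t <- peek()
  if (t$type != "eof")
    stop(sprintf("query syntax error at column %d: unexpected '%s'",
                 t$col, t$lex))
  ast
}

# ---- evaluation --------------------------------------------------------

.atomPropTable <- function(x) {
  a <- atoms(x)
  data.frame(id = a$id, aname = a$name, rname = a$resname, rnum = a$resnum,
             cname = a$chain, ele = a$element, occ = a$occ, abfac = a$bfac,
             ishetatm = a$ishetatm, charge = a$charge, resId = a$resId,
             chainId = a$chainId, stringsAsFactors = FALSE)
}

.genericColumn <- function(x, prop, tab) {
  h <- .handleOf(x)
  level <- switch(substr(prop, 1, 2), ga = "atom", gr = "residue",
                  gc = "chain")
  key <- substr(prop, 4, nchar(prop))
  ids <- switch(level, atom = tab$id, residue = tab$resId, chain = tab$chainId)
  uids <- unique(ids)
  vals <- lapply(uids, function(i) {
    k <- .propKey(level, i, key)
    if (exists(k, envir = h@ptr$props, inherits = FALSE))
      get(k, envir = h@ptr$props, inherits = FALSE)$value else NULL
  })
  names(vals) <- as.character(uids)
  vals[as.character(ids)]
}

.evalNode <- function(node, x, tab) {
  switch(node$kind,
    and = .evalNode(node$left, x, tab) & .evalNode(node$right, x, tab),
    or  = .evalNode(node$left, x, tab) | .evalNode(node$right, x, tab),
    not = !.evalNode(node$expr, x, tab),
    within = {
      refPos <- if (!is.null(node$point)) {
        matrix(node$point, 1, 3)
      } else {
        sub <- .evalNode(node$ref, x, tab)
        positions(x)[sub, , drop = FALSE]
      }
      tab$id %in% .withinAnyOf(x, refPos, node$radius)
    },
    predicate = .evalPredicate(node, x, tab),
    stop("malformed query AST"))
}

.evalPredicate <- function(node, x, tab) {
  prop <- node$prop; op <- node$op
  generic <- grepl("^g[arc]:", prop)
  if (generic) {
    vals <- .genericColumn(x, prop, tab)
    present <- !vapply(vals, is.null, logical(1))
    res <- rep(FALSE, nrow(tab))
    if (!any(present)) return(res)
    # compare per stored type; absent key never matches
    cmp <- function(v) .compareScalar(v, op, node$values, prop)
    res[present] <- vapply(vals[present], cmp, logical(1))
    return(res)
  }
  colv <- tab[[prop]]
  numeric <- prop %in% .numericProps
  if (prop == "ishetatm") {
    vals <- vapply(node$values, function(v) v$str, character(1))
    if (!op %in% c("=", "!="))
      stop("type mismatch: 'ishetatm' supports only = and !=")
    want <- vals %in% c("true", "1", "TRUE")
    bad <- !vals %in% c("true", "false", "1", "0", "TRUE", "FALSE")
    if (any(bad)) stop("invalid boolean value for ishetatm: ", vals[bad][1])
    hit <- colv %in% want
    return(if (op == "=") hit else !hit)
  }
  if (op %in% c("<", "<=", ">", ">=")) {
    if (!numeric)
      stop("type mismatch: relational comparison on text property '",
           prop, "'")
    v <- node$values[[1]]$num
    return(switch(op, "<" = colv < v, "<=" = colv <= v,
                  ">" = colv > v, ">=" = colv >= v))
  }
  # = / != with value list and optional ranges
  hit <- rep(FALSE, length(colv))
  for (v in node$values) {
    if (v$kind == "range") {
      if (!numeric)
        stop("type mismatch: range on text property '", prop, "'")
      hit <- hit | (colv >= v$lo & colv <= v$hi)
    } else if (numeric) {
      if (is.na(v$num))
        stop("type mismatch: non-numeric value '", v$str,
             "' for numeric property '", prop, "'")
      hit <- hit | (colv == v$num)
    } else {
      hit <- hit | (colv == v$str)
    }
  }
  if (op == "=") hit else !hit
}

.compareScalar <- function(value, op, valueNodes, prop) {
  if (is.logical(value)) {
    if (!op %in% c("=", "!="))
      stop("type mismatch: boolean generic property '", prop,
           "' supports only = and !=")
    want <- vapply(valueNodes, function(v)
      v$str %in% c("true", "1", "TRUE"), logical(1))
    hit <- any(value == want)
    return(if (op == "=") hit else !hit)
  }
  if (is.numeric(value)) {
    if (op %in% c("<", "<=", ">", ">=")) {
      v <- valueNodes[[1]]$num
      return(switch(op, "<" = value < v, "<=" = value <= v,
                    ">" = value > v, ">=" = value >= v))
    }
    hit <- FALSE
    for (v in valueNodes) {
      if (v$kind == "range") hit <- hit || (value >= v$lo && value <= v$hi)
      else {
        if (is.na(v$num))
          stop("type mismatch: non-numeric value '", v$str,
               "' for numeric generic property '", prop, "'")
        hit <- hit || (value == v$num)
      }
    }
    return(if (op == "=") hit else !hit)
  }
  # text
  if (!op %in% c("=", "!="))
    stop("type mismatch: relational comparison on text generic property '",
         prop, "'")
  hit <- any(vapply(valueNodes, function(v) identical(v$str, value),
                    logical(1)))
  if (op == "=") hit else !hit
}

#' @rdname queryLanguage
#' @param ast a parsed query as returned by \code{parseQuery}.
#' @export
evaluateQuery <- function(x, ast) {
  tab <- .atomPropTable(x)
  if (!nrow(tab))
    return(new("EntityView", handle = .handleOf(x), atomIds = integer(),
               generation = .handleOf(x)@ptr$generation))
  hit <- .evalNode(ast, x, tab)
  createView(x, sort(tab$id[hit]))
}

#' @rdname queryLanguage
#' @export
select <- function(x, query) evaluateQuery(x, parseQuery(query))
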