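#' @title Deterministic OWL functional-syntax and OBO serialization
#' @description
#' OWL 2 Functional-Style Syntax is the canonical interchange format: it is
#' line-oriented and diffable, and the supported fragment (declarations,
#' SubClassOf/EquivalentClasses over intersection, existential and
#' has-value restrictions, assertions, annotations, property
#' characteristics and the exemplar property chain) covers everything the
#' builder emits. Writing is canonical — declarations first, axioms sorted
#' — so equal documents produce byte-equal files and
#' \code{write(parse(write(x)))} is a fixed point. Constructs outside the
#' fragment fail parsing with an explicit unsupported-construct error and
#' location. An OBO 1.4 writer provides a documented lossy convenience
#' export (id, name, is_a from the reduced hierarchy, definitions,
#' synonyms).
#' @name owl-serialization
NULL

decl_keyword <- c(class = "Class", individual = "NamedIndividual",
                  object_property = "ObjectProperty",
                  annotation_property = "AnnotationProperty")

#' Serialize an ontology document to OWL functional syntax
#'
#' @param doc ontology document.
#' @param path optional output file; when NULL the text is returned.
#' @return character vector of lines (invisibly when writing to a file).
#' @export
write_functional_syntax <- function(doc, path = NULL) {
  und <- undeclared_identifiers(doc)
  if (length(und))
    stop_ccn("UNDECLARED", "axioms use unregistered identifier(s): %s",
             paste(und, collapse = ", "))
  used_prefixes <- unique(curie_prefix(doc$entities$id))
  missing <- setdiff(used_prefixes, names(doc$prefixes))
  if (length(missing))
    stop_ccn("UNKNOWN_PREFIX", "no IRI registered for prefix(es): %s",
             paste(missing, collapse = ", "))
  pf <- doc$prefixes[canonical_order(names(doc$prefixes))]
  lines <- c(sprintf("Prefix(%s:=<%s>)", names(pf), unname(pf)),
             "",
             sprintf("Ontology(<%s>", doc$iri))
  decls <- sprintf("Declaration(%s(%s))",
                   decl_keyword[doc$entities$kind], doc$entities$id)
  lines <- c(lines, canonical_sort(decls),
             vapply(doc$axioms, render_axiom, character(1)),
             ")")
  if (is.null(path)) return(lines)
  write_lines_utf8(lines, path)
  invisible(lines)
}

## ---- parsing -----------------------------------------------------------

tokenize_fss <- function(text) {
  src <- paste(text, collapse = "\n")
  n <- nchar(src)
  toks <- list(); i <- 1L; line <- 1L; col <- 1L
  push <- function(type, value) toks[[length(toks) + 1L]] <<-
    list(type = type, value = value, line = line, col = col)
  while (i <= n) {
    ch <- substr(src, i, i)
    if (ch == "\n") { line <- line + 1L; col <- 1L; i <- i + 1L; next }
    if (grepl("^[ \t\r]$", ch)) { i <- i + 1L; col <- col + 1L; next }
    if (ch == "#") {  # line comment
      while (i <= n && substr(src, i, i) != "\n") i <- i + 1L
      next
    }
    if (ch == "(") { push("lpar", "("); i <- i + 1L; col <- col + 1L; next }
    if (ch == ")") { push("rpar", ")"); i <- i + 1L; col <- col + 1L; next }
    if (ch == "<") {
      j <- regexpr(">", substr(src, i, n), fixed = TRUE)
      if (j == -1L) stop_ccn("SYNTAX", "unterminated IRI at line %d col %d",
                             line, col)
      push("iri", substr(src, i + 1L, i + j - 2L))
      col <- col + j; i <- i + j; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character(0)
      while (j <= n) {
        cj <- substr(src, j, j)
        if (cj == "\\") { buf <- c(buf, substr(src, j + 1L, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        buf <- c(buf, cj); j <- j + 1L
      }
      if (j > n) stop_ccn("SYNTAX", "unterminated string at line %d col %d",
                          line, col)
      val <- paste(buf, collapse = "")
      i <- j + 1L
      dt <- NULL
      if (substr(src, i, i + 1L) == "^^") {
        m <- regmatches(substr(src, i + 2L, n),
                        regexpr("^[A-Za-z_][A-Za-z0-9_.]*:[^\\s()]+",
                                substr(src, i + 2L, n), perl = TRUE))
        if (!length(m)) stop_ccn("SYNTAX", "malformed datatype at line %d", line)
        dt <- m; i <- i + 2L + nchar(m)
      }
      push("literal", list(value = val, datatype = dt))
      next
    }
    nm <- regmatches(substr(src, i, n),
                     regexpr("^[0-9]+(\\.[0-9]+)?", substr(src, i, n),
                             perl = TRUE))
    if (length(nm) && nzchar(nm)) {  # bare number (cardinalities etc.)
      push("number", nm)
      col <- col + nchar(nm); i <- i + nchar(nm); next
    }
    m <- regmatches(substr(src, i, n),
                    regexpr("^[A-Za-z_][A-Za-z0-9_.-]*(:=|:[^\\s()]+)?",
                            substr(src, i, n), perl = TRUE))
    if (length(m) && nzchar(m)) {
      if (endsWith(m, ":=")) push("prefixdef", sub(":=$", "", m))
      else if (grepl(":", m, fixed = TRUE)) push("curie", m)
      else push("keyword", m)
      col <- col + nchar(m); i <- i + nchar(m); next
    }
    stop_ccn("SYNTAX", "unexpected character '%s' at line %d col %d",
             ch, line, col)
  }
  toks
}

#' Parse OWL functional syntax into an ontology document
#'
#' Inverse of \code{\link{write_functional_syntax}} on the canonical form.
#' Constructs outside the supported fragment (cardinality, union,
#' complement, data restrictions, ...) raise an explicit
#' unsupported-construct error naming the construct and its location.
#'
#' @param x path to a file, or a character vector of lines.
#' @export
parse_functional_syntax <- function(x) {
  text <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE,
                                                           encoding = "UTF-8")
          else x
  toks <- tokenize_fss(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  nxt <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- nxt()
    if (is.null(t) || t$type != type)
      stop_ccn("SYNTAX", "expected %s at line %d", type,
               if (is.null(t)) -1L else t$line)
    t
  }
  fail_unsupported <- function(t)
    stop_ccn("UNSUPPORTED", "unsupported construct '%s' at line %d col %d",
             t$value, t$line, t$col)

  prefixes <- character(0)
  entities <- data.frame(id = character(0), kind = character(0),
                         stringsAsFactors = FALSE)
  axioms <- list()
  iri <- default_config()$ontology_iri

  parse_expr <- function() {
    t <- nxt()
    if (t$type == "curie") return(ce_class(t$value))
    if (t$type != "keyword") stop_ccn("SYNTAX", "expected expression at line %d",
                                      t$line)
    switch(t$value,
      ObjectIntersectionOf = {
        expect("lpar")
        args <- list()
        while (!is.null(peek()) && peek()$type != "rpar")
          args <- c(args, list(parse_expr()))
        expect("rpar")
        do.call(ce_and, args)
      },
      ObjectSomeValuesFrom = {
        expect("lpar")
        p <- expect("curie")$value
        f <- parse_expr()
        expect("rpar")
        ce_some(p, f)
      },
      ObjectHasValue = {
        expect("lpar")
        p <- expect("curie")$value
        ind <- expect("curie")$value
        expect("rpar")
        ce_value(p, ind)
      },
      fail_unsupported(t))
  }

  parse_value <- function() {
    t <- nxt()
    if (t$type == "curie") return(iri(t$value))
    if (t$type == "literal")
      return(structure(list(kind = "literal", value = t$value$value,
                            datatype = t$value$datatype),
                       class = "owl_value"))
    stop_ccn("SYNTAX", "expected annotation value at line %d", t$line)
  }

  parse_axiom <- function(t) {
    switch(t$value,
      Declaration = {
        expect("lpar")
        kt <- expect("keyword")
        kind <- names(decl_keyword)[decl_keyword == kt$value]
        if (!length(kind)) fail_unsupported(kt)
        expect("lpar")
        id <- expect("curie")$value
        expect("rpar"); expect("rpar")
        entities <<- rbind(entities, data.frame(id = id, kind = kind,
                                                stringsAsFactors = FALSE))
        NULL
      },
      SubClassOf = {
        expect("lpar")
        sub <- parse_expr()
        sup <- parse_expr()
        expect("rpar")
        if (sub$type != "Class")
          stop_ccn("UNSUPPORTED",
                   "only named subclasses are supported (line %d)", t$line)
        ax_subclass(sub$id, sup)
      },
      EquivalentClasses = {
        expect("lpar")
        a <- parse_expr(); b <- parse_expr()
        expect("rpar")
        if (a$type != "Class")
          stop_ccn("UNSUPPORTED",
                   "first EquivalentClasses operand must be named (line %d)",
                   t$line)
        ax_equivalent(a$id, b)
      },
      ClassAssertion = {
        expect("lpar")
        e <- parse_expr()
        ind <- expect("curie")$value
        expect("rpar")
        ax_class_assertion(e, ind)
      },
      ObjectPropertyAssertion = {
        expect("lpar")
        p <- expect("curie")$value
        s <- expect("curie")$value
        o <- expect("curie")$value
        expect("rpar")
        ax_obj_assertion(p, s, o)
      },
      AnnotationAssertion = {
        expect("lpar")
        p <- expect("curie")$value
        s <- expect("curie")$value
        v <- parse_value()
        expect("rpar")
        ax_annotation(p, s, v)
      },
      TransitiveObjectProperty = {
        expect("lpar"); p <- expect("curie")$value; expect("rpar")
        ax_transitive(p)
      },
      SymmetricObjectProperty = {
        expect("lpar"); p <- expect("curie")$value; expect("rpar")
        ax_symmetric(p)
      },
      SubObjectPropertyOf = {
        expect("lpar")
        k <- nxt()
        if (k$type != "keyword" || k$value != "ObjectPropertyChain")
          fail_unsupported(k)
        expect("lpar")
        chain <- character(0)
        while (!is.null(peek()) && peek()$type == "curie")
          chain <- c(chain, nxt()$value)
        expect("rpar")
        super <- expect("curie")$value
        expect("rpar")
        ax_property_chain(chain, super)
      },
      fail_unsupported(t))
  }

  while (!is.null(peek())) {
    t <- nxt()
    if (t$type == "keyword" && t$value == "Prefix") {
      expect("lpar")
      pd <- expect("prefixdef")$value
      pi <- expect("iri")$value
      expect("rpar")
      prefixes[pd] <- pi
    } else if (t$type == "keyword" && t$value == "Ontology") {
      expect("lpar")
      if (!is.null(peek()) && peek()$type == "iri") iri <- nxt()$value
      while (!is.null(peek()) && peek()$type != "rpar") {
        at <- nxt()
        if (at$type != "keyword")
          stop_ccn("SYNTAX", "expected axiom at line %d", at$line)
        ax <- parse_axiom(at)
        if (!is.null(ax)) axioms <- c(axioms, list(ax))
      }
      expect("rpar")
    } else {
      stop_ccn("SYNTAX", "unexpected token '%s' at line %d",
               paste(t$value, collapse = ""), t$line)
    }
  }
  ontology_document(entities = entities, axioms = axioms,
                    prefixes = prefixes, iri = iri)
}

## ---- OBO export --------------------------------------------------------

#' Lossy OBO 1.4 export
#'
#' One [Term] stanza per class: id, name from the label annotation, def
#' from the definition annotation, one sorted synonym line per synonym,
#' is_a lines from the transitively reduced hierarchy (named pairs only),
#' and an xref to the source cluster accession when present. Everything
#' else in the document (individuals, assertions, restrictions) is
#' documented as not exported. Deterministic.
#'
#' @param doc ontology document.
#' @param hierarchy reduced \code{\link{inferred_hierarchy}} supplying the
#'   is_a lines (NULL: asserted named SubClassOf axioms are used).
#' @param path optional output file.
#' @export
write_obo <- function(doc, hierarchy = NULL, path = NULL,
                      config = default_config()) {
  v <- config$vocabulary
  classes <- entities_of_kind(doc, "class")
  is_a <- if (!is.null(hierarchy)) {
    stats::setNames(split(hierarchy$pairs$sup,
                          factor(hierarchy$pairs$sub, levels = classes)),
                    classes)
  } else {
    named <- Filter(function(a) a$sup$type == "Class",
                    axioms_of_type(doc, "SubClassOf"))
    split(vapply(named, function(a) a$sup$id, character(1)),
          factor(vapply(named, `[[`, character(1), "sub"), levels = classes))
  }
  labels <- annotation_map(doc, v$label)
  lines <- c("format-version: 1.4",
             sprintf("ontology: %s", doc$iri), "")
  for (cid in classes) {
    anns <- annotations_for(doc, cid)
    lines <- c(lines, "[Term]", sprintf("id: %s", cid))
    nm <- anns[[v$label]] %||% local_name(cid)
    lines <- c(lines, sprintf("name: %s", nm[1]))
    def <- anns[[v$definition]]
    if (!is.null(def))
      lines <- c(lines, sprintf("def: \"%s\" []", gsub("\"", "'", def[1])))
    for (syn in canonical_sort(unique(anns[[v$synonym]] %||% character(0))))
      lines <- c(lines, sprintf("synonym: \"%s\" EXACT []",
                                gsub("\"", "'", syn)))
    acc <- anns[[v$accession]]
    if (!is.null(acc)) lines <- c(lines, sprintf("xref: %s", acc[1]))
    for (p in canonical_sort(unique(is_a[[cid]] %||% character(0)))) {
      pl <- labels[p]
      lines <- c(lines, sprintf("is_a: %s%s", p,
                                if (!is.na(pl)) paste0(" ! ", pl) else ""))
    }
    lines <- c(lines, "")
  }
  lines <- lines[-length(lines)]
  if (is.null(path)) return(lines)
  write_lines_utf8(lines, path)
  invisible(lines)
}
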