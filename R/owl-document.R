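#' @title In-memory OWL 2 fragment
#' @description
#' The pipeline works on a minimal OWL 2 fragment sufficient for the schema:
#' named classes, individuals, object and annotation properties;
#' SubClassOf / EquivalentClasses with class expressions built from
#' intersection, existential restriction and has-value restriction;
#' ClassAssertion, ObjectPropertyAssertion, AnnotationAssertion; and the
#' property characteristics the schema relies on (transitivity, symmetry,
#' the exemplar property chain). Axioms are kept in canonical (sorted,
#' deduplicated) order so serialization is byte-deterministic.
#' @name owl-document
NULL

## ---- class expressions -------------------------------------------------

#' Class expression constructors
#'
#' \code{ce_class} names a class; \code{ce_and} intersects expressions;
#' \code{ce_some} is an existential restriction; \code{ce_value} a has-value
#' restriction on an individual. Plain CURIE strings are accepted wherever an
#' expression is expected and coerced with \code{ce_class}.
#'
#' @param id class CURIE.
#' @export
ce_class <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(type = "Class", id = id), class = "owl_expr")
}

#' @rdname ce_class
#' @param ... sub-expressions (at least two).
#' @export
ce_and <- function(...) {
  args <- lapply(list(...), as_expr)
  stopifnot(length(args) >= 2L)
  structure(list(type = "And", args = args), class = "owl_expr")
}

#' @rdname ce_class
#' @param property object-property CURIE.
#' @param filler class expression (or CURIE).
#' @export
ce_some <- function(property, filler) {
  structure(list(type = "Some", property = property, filler = as_expr(filler)),
            class = "owl_expr")
}

#' @rdname ce_class
#' @param individual individual CURIE.
#' @export
ce_value <- function(property, individual) {
  structure(list(type = "Value", property = property, individual = individual),
            class = "owl_expr")
}

as_expr <- function(x) {
  if (inherits(x, "owl_expr")) return(x)
  if (is.character(x) && length(x) == 1L) return(ce_class(x))
  stop_ccn("EXPR_TYPE", "cannot interpret object of class %s as a class expression",
           paste(class(x), collapse = "/"))
}

## ---- literals ----------------------------------------------------------

#' Typed literal for annotation values
#' @param value scalar character, numeric or logical.
#' @export
lit <- function(value) {
  if (is.numeric(value))
    structure(list(kind = "literal", value = format_shortest(value),
                   datatype = "xsd:double"), class = "owl_value")
  else if (is.logical(value))
    structure(list(kind = "literal", value = tolower(as.character(value)),
                   datatype = "xsd:boolean"), class = "owl_value")
  else
    structure(list(kind = "literal", value = as.character(value),
                   datatype = NULL), class = "owl_value")
}

#' IRI-valued annotation target
#' @param id CURIE.
#' @export
iri <- function(id) structure(list(kind = "iri", value = id), class = "owl_value")

as_owl_value <- function(x) if (inherits(x, "owl_value")) x else lit(x)

## ---- axioms ------------------------------------------------------------

new_axiom <- function(type, ...) {
  structure(list(type = type, ...), class = "owl_axiom")
}

#' Axiom constructors for the supported OWL fragment
#'
#' @param sub named subclass CURIE.
#' @param sup superclass expression.
#' @export
ax_subclass <- function(sub, sup) new_axiom("SubClassOf", sub = sub,
                                            sup = as_expr(sup))

#' @rdname ax_subclass
#' @param id named class CURIE.
#' @param expr equivalent class expression.
#' @export
ax_equivalent <- function(id, expr) new_axiom("EquivalentClasses", id = id,
                                              expr = as_expr(expr))

#' @rdname ax_subclass
#' @param expr class expression the individual instantiates.
#' @param individual individual CURIE.
#' @export
ax_class_assertion <- function(expr, individual)
  new_axiom("ClassAssertion", expr = as_expr(expr), individual = individual)

#' @rdname ax_subclass
#' @param property object-property CURIE.
#' @param subject,object individual CURIEs.
#' @export
ax_obj_assertion <- function(property, subject, object)
  new_axiom("ObjectPropertyAssertion", property = property,
            subject = subject, object = object)

#' @rdname ax_subclass
#' @param value annotation value (string/number/\code{\link{lit}}/\code{\link{iri}}).
#' @export
ax_annotation <- function(property, subject, value)
  new_axiom("AnnotationAssertion", property = property, subject = subject,
            value = as_owl_value(value))

#' @rdname ax_subclass
#' @export
ax_transitive <- function(property) new_axiom("TransitiveObjectProperty",
                                              property = property)

#' @rdname ax_subclass
#' @export
ax_symmetric <- function(property) new_axiom("SymmetricObjectProperty",
                                             property = property)

#' @rdname ax_subclass
#' @param chain character vector of property CURIEs composed left to right.
#' @param super property the chain is a subproperty of.
#' @export
ax_property_chain <- function(chain, super)
  new_axiom("SubPropertyChainOf", chain = chain, super = super)

## ---- document ----------------------------------------------------------

entity_kinds <- c("class", "individual", "object_property", "annotation_property")

#' Construct an ontology document
#'
#' @param entities data.frame with columns \code{id}, \code{kind}.
#' @param axioms list of axioms (see \code{\link{ax_subclass}}).
#' @param prefixes named character vector of CURIE prefixes.
#' @param iri ontology IRI.
#' @export
ontology_document <- function(entities = NULL, axioms = list(),
                              prefixes = default_config()$prefixes,
                              iri = default_config()$ontology_iri) {
  if (is.null(entities))
    entities <- data.frame(id = character(0), kind = character(0),
                           stringsAsFactors = FALSE)
  stopifnot(all(entities$kind %in% entity_kinds))
  doc <- structure(list(entities = entities, axioms = axioms,
                        prefixes = prefixes, iri = iri),
                   class = "ontology_document")
  canonicalize_document(doc)
}

#' Declare entities in a document
#' @param doc ontology document.
#' @param ids CURIEs to declare.
#' @param kind one of class, individual, object_property, annotation_property.
#' @export
declare <- function(doc, ids, kind) {
  kind <- match.arg(kind, entity_kinds)
  add <- data.frame(id = ids, kind = kind, stringsAsFactors = FALSE)
  doc$entities <- rbind(doc$entities, add)
  canonicalize_document(doc)
}

#' Append axioms to a document
#' @param doc ontology document.
#' @param ... axioms or lists of axioms.
#' @export
add_axioms <- function(doc, ...) {
  new <- list(...)
  flat <- list()
  for (x in new) {
    if (inherits(x, "owl_axiom")) flat <- c(flat, list(x))
    else flat <- c(flat, x)
  }
  doc$axioms <- c(doc$axioms, flat)
  canonicalize_document(doc)
}

canonicalize_document <- function(doc) {
  ent <- unique(doc$entities)
  dup <- ent$id[duplicated(ent$id)]
  if (length(dup))
    stop_ccn("DECL_CONFLICT",
             "identifier(s) declared with conflicting kinds: %s",
             paste(unique(dup), collapse = ", "))
  ent <- ent[canonical_order(ent$id), , drop = FALSE]
  rownames(ent) <- NULL
  doc$entities <- ent
  if (length(doc$axioms)) {
    keys <- vapply(doc$axioms, render_axiom, character(1))
    keep <- !duplicated(keys)
    doc$axioms <- doc$axioms[keep][canonical_order(keys[keep])]
  }
  doc
}

#' Merge ontology documents
#'
#' Union of entities and axioms, deduplicated and canonically ordered; a
#' declaration conflict (same identifier, different kind) is a hard error.
#' Merging is commutative and idempotent up to canonical ordering.
#'
#' @param ... ontology documents (or a single list of them).
#' @export
merge_ontologies <- function(...) {
  docs <- list(...)
  if (length(docs) == 1L && !inherits(docs[[1]], "ontology_document"))
    docs <- docs[[1]]
  stopifnot(length(docs) >= 1L)
  out <- docs[[1]]
  for (d in docs[-1]) {
    stopifnot(inherits(d, "ontology_document"))
    out$entities <- rbind(out$entities, d$entities)
    out$axioms <- c(out$axioms, d$axioms)
    pf <- c(out$prefixes, d$prefixes)
    out$prefixes <- pf[!duplicated(names(pf))]
  }
  canonicalize_document(out)
}

# check every identifier used in axioms is declared
undeclared_identifiers <- function(doc) {
  used <- unique(unlist(lapply(doc$axioms, axiom_identifiers)))
  setdiff(used, doc$entities$id)
}

axiom_identifiers <- function(ax) {
  expr_ids <- function(e) switch(e$type,
    Class = e$id,
    And = unlist(lapply(e$args, expr_ids)),
    Some = c(e$property, expr_ids(e$filler)),
    Value = c(e$property, e$individual))
  switch(ax$type,
    SubClassOf = c(ax$sub, expr_ids(ax$sup)),
    EquivalentClasses = c(ax$id, expr_ids(ax$expr)),
    ClassAssertion = c(expr_ids(ax$expr), ax$individual),
    ObjectPropertyAssertion = c(ax$property, ax$subject, ax$object),
    AnnotationAssertion = c(ax$property, ax$subject,
                            if (ax$value$kind == "iri") ax$value$value),
    TransitiveObjectProperty = ax$property,
    SymmetricObjectProperty = ax$property,
    SubPropertyChainOf = c(ax$chain, ax$super))
}

#' @export
print.ontology_document <- function(x, ...) {
  kinds <- table(factor(x$entities$kind, levels = entity_kinds))
  cat(sprintf(paste0("<ontology_document> %d entities ",
                     "(%d classes, %d individuals, %d obj-props, %d ann-props), ",
                     "%d axioms\n"),
              nrow(x$entities), kinds[["class"]], kinds[["individual"]],
              kinds[["object_property"]], kinds[["annotation_property"]],
              length(x$axioms)))
  invisible(x)
}

## ---- rendering (functional-style syntax) -------------------------------

render_expr <- function(e) {
  switch(e$type,
    Class = e$id,
    And = paste0("ObjectIntersectionOf(",
                 paste(vapply(e$args, render_expr, character(1)),
                       collapse = " "), ")"),
    Some = paste0("ObjectSomeValuesFrom(", e$property, " ",
                  render_expr(e$filler), ")"),
    Value = paste0("ObjectHasValue(", e$property, " ", e$individual, ")"),
    stop_ccn("RENDER", "unknown expression type %s", e$type))
}

render_value <- function(v) {
  if (v$kind == "iri") return(v$value)
  s <- paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", v$value)), "\"")
  if (!is.null(v$datatype)) paste0(s, "^^", v$datatype) else s
}

render_axiom <- function(ax) {
  switch(ax$type,
    SubClassOf = paste0("SubClassOf(", ax$sub, " ", render_expr(ax$sup), ")"),
    EquivalentClasses = paste0("EquivalentClasses(", ax$id, " ",
                               render_expr(ax$expr), ")"),
    ClassAssertion = paste0("ClassAssertion(", render_expr(ax$expr), " ",
                            ax$individual, ")"),
    ObjectPropertyAssertion = paste0("ObjectPropertyAssertion(", ax$property,
                                     " ", ax$subject, " ", ax$object, ")"),
    AnnotationAssertion = paste0("AnnotationAssertion(", ax$property, " ",
                                 ax$subject, " ", render_value(ax$value), ")"),
    TransitiveObjectProperty = paste0("TransitiveObjectProperty(", ax$property, ")"),
    SymmetricObjectProperty = paste0("SymmetricObjectProperty(", ax$property, ")"),
    SubPropertyChainOf = paste0("SubObjectPropertyOf(ObjectPropertyChain(",
                                paste(ax$chain, collapse = " "), ") ",
                                ax$super, ")"),
    stop_ccn("RENDER", "unknown axiom type %s", ax$type))
}

## ---- convenient accessors used by downstream modules --------------------

entities_of_kind <- function(doc, kind) doc$entities$id[doc$entities$kind == kind]

axioms_of_type <- function(doc, type) {
  doc$axioms[vapply(doc$axioms, function(a) a$type == type, logical(1))]
}

# named character vector subject -> annotation value for a given property
annotation_map <- function(doc, property) {
  anns <- axioms_of_type(doc, "AnnotationAssertion")
  anns <- anns[vapply(anns, function(a) a$property == property, logical(1))]
  stats::setNames(vapply(anns, function(a) a$value$value, character(1)),
                  vapply(anns, function(a) a$subject, character(1)))
}

# all annotation values for one subject as a named list of character vectors
annotations_for <- function(doc, subject) {
  anns <- axioms_of_type(doc, "AnnotationAssertion")
  anns <- anns[vapply(anns, function(a) a$subject == subject, logical(1))]
  out <- list()
  for (a in anns) out[[a$property]] <- c(out[[a$property]], a$value$value)
  out
}
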