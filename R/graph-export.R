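#' @title Projection to a labelled property graph
#' @description
#' Emulates the neo4j2owl-style projection that drives the application
#' layer: every class and individual becomes a node carrying its
#' annotations as properties; entailed and asserted subsumption (after
#' transitive reduction) becomes \code{is_a} edges with a provenance
#' property; existential restrictions to named fillers, exemplar has-value
#' equivalences and object-property assertions become typed edges. The
#' syntactic complexities of OWL do not survive the projection, but its
#' entailments and annotations do. Semantic tags — simple strings driving
#' faceted search — are added by declarative rules over the inferred
#' hierarchy and asserted restrictions.
#' @name graph-export
NULL

local_name <- function(id) sub("^[^:]*:", "", id)

#' Project a reasoned ontology into a property graph
#'
#' @param doc merged ontology document.
#' @param hierarchy \code{\link{inferred_hierarchy}} (transitively reduced)
#'   whose pairs become \code{is_a} edges.
#' @param config build configuration.
#' @return a \code{property_graph}: list with \code{nodes} and \code{edges}
#'   data.frames.
#' @export
project_graph <- function(doc, hierarchy, config = default_config()) {
  v <- config$vocabulary
  keep <- doc$entities$kind %in% c("class", "individual")
  ids <- doc$entities$id[keep]
  kinds <- c(class = "Class", individual = "Individual")[doc$entities$kind[keep]]
  anns <- list()
  for (ax in axioms_of_type(doc, "AnnotationAssertion"))
    anns[[ax$subject]] <- c(anns[[ax$subject]],
                            stats::setNames(list(ax$value$value), ax$property))
  nodes <- do.call(rbind, lapply(seq_along(ids), function(i) {
    id <- ids[i]
    a <- anns[[id]]
    vals <- function(p) canonical_sort(unique(unlist(a[names(a) == p])))
    rest <- a[!(names(a) %in% c(v$label, v$synonym))]
    rest_keys <- canonical_sort(unique(names(rest)))
    props <- if (length(rest_keys) == 0L) "{}" else
      as.character(jsonlite::toJSON(
        stats::setNames(lapply(rest_keys, function(k)
          canonical_sort(unique(unlist(rest[names(rest) == k])))), rest_keys)))
    data.frame(id = id, labels = unname(kinds[i]),
               name = (vals(v$label) %||% local_name(id))[1],
               synonyms = join_multi(vals(v$synonym)),
               tags = "", properties = props, stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) nodes <- data.frame(id = character(0), labels = character(0),
                                          name = character(0), synonyms = character(0),
                                          tags = character(0), properties = character(0))
  edges <- data.frame(from = character(0), to = character(0),
                      type = character(0), provenance = character(0),
                      stringsAsFactors = FALSE)
  add_edge <- function(from, to, type, provenance = "") {
    edges <<- rbind(edges, data.frame(from = from, to = to, type = type,
                                      provenance = provenance,
                                      stringsAsFactors = FALSE))
  }
  if (!is.null(hierarchy))
    for (i in seq_len(nrow(hierarchy$pairs)))
      add_edge(hierarchy$pairs$sub[i], hierarchy$pairs$sup[i], "is_a",
               hierarchy$pairs$provenance[i])
  for (ax in axioms_of_type(doc, "SubClassOf"))
    if (ax$sup$type == "Some" && ax$sup$filler$type == "Class")
      add_edge(ax$sub, ax$sup$filler$id, local_name(ax$sup$property))
  for (ax in axioms_of_type(doc, "EquivalentClasses")) {
    e <- ax$expr
    if (e$type == "And")
      for (arg in e$args)
        if (arg$type == "Value")
          add_edge(ax$id, arg$individual, local_name(arg$property))
  }
  for (ax in axioms_of_type(doc, "ObjectPropertyAssertion"))
    add_edge(ax$subject, ax$object, local_name(ax$property))
  edges <- edges[!duplicated(paste(edges$from, edges$to, edges$type)), ,
                 drop = FALSE]
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(missing))
    stop_ccn("DANGLING_EDGE", "edge endpoint(s) not projected as nodes: %s",
             paste(missing, collapse = ", "))
  new_property_graph(nodes, edges)
}

new_property_graph <- function(nodes, edges) {
  nodes <- nodes[canonical_order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[canonical_order(paste(edges$from, edges$to, edges$type)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "property_graph")
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("<property_graph> %d nodes, %d edges, %d tagged node(s)\n",
              nrow(x$nodes), nrow(x$edges), sum(nzchar(x$nodes$tags))))
  invisible(x)
}

#' Declarative semantic-tag rule
#'
#' A node receives \code{tag} iff it satisfies all conditions present:
#' being the target of \code{requires_subclass_of} or below it in the
#' inferred hierarchy, and carrying an asserted restriction
#' \code{property some filler} (with the filler compared up to subclass
#' closure when \code{filler_closure}). At least one condition is
#' required. This restricted declarative form covers the tag queries the
#' application layer needs (species, region, gross class, morphology,
#' projection) without embedding a DL or SPARQL engine.
#'
#' @param tag tag string.
#' @param requires_subclass_of class CURIE or NULL.
#' @param requires_restriction NULL or list(property, filler,
#'   filler_closure = TRUE).
#' @export
tag_rule <- function(tag, requires_subclass_of = NULL,
                     requires_restriction = NULL) {
  if (is.null(requires_subclass_of) && is.null(requires_restriction))
    stop_ccn("EMPTY_RULE", "tag rule '%s' has no condition", tag)
  structure(list(tag = tag, requires_subclass_of = requires_subclass_of,
                 requires_restriction = requires_restriction),
            class = "tag_rule")
}

#' Apply semantic-tag rules to a property graph
#'
#' @param graph property graph from \code{\link{project_graph}}.
#' @param rules list of \code{\link{tag_rule}}.
#' @param hierarchy inferred hierarchy the subclass conditions are
#'   evaluated against.
#' @param doc ontology document supplying the asserted restrictions.
#' @return the graph with the \code{tags} node property populated (sorted,
#'   "|"-separated).
#' @export
apply_tags <- function(graph, rules, hierarchy, doc,
                       config = default_config()) {
  cl <- hierarchy_closure(hierarchy)
  below <- split(cl$pairs$sub, factor(cl$pairs$sup,
                                      levels = unique(c(cl$pairs$sub,
                                                        cl$pairs$sup))))
  restr <- list()
  for (ax in axioms_of_type(doc, "SubClassOf"))
    if (ax$sup$type == "Some" && ax$sup$filler$type == "Class")
      restr[[ax$sub]] <- c(restr[[ax$sub]],
                           list(c(ax$sup$property, ax$sup$filler$id)))
  filler_below <- function(f, target, closed) {
    f == target || (closed && f %in% (below[[target]] %||% character(0)))
  }
  tags <- stats::setNames(vector("list", nrow(graph$nodes)), graph$nodes$id)
  for (rule in rules) {
    for (ref in c(rule$requires_subclass_of,
                  rule$requires_restriction$property,
                  rule$requires_restriction$filler))
      if (!(ref %in% doc$entities$id))
        stop_ccn("UNKNOWN_RULE_ID", "tag rule '%s' references undeclared %s",
                 rule$tag, ref)
    for (id in graph$nodes$id) {
      ok <- TRUE
      if (!is.null(rule$requires_subclass_of)) {
        t <- rule$requires_subclass_of
        ok <- id == t || id %in% (below[[t]] %||% character(0))
      }
      if (ok && !is.null(rule$requires_restriction)) {
        rr <- rule$requires_restriction
        closed <- isTRUE(rr$filler_closure %||% TRUE)
        ok <- any(vapply(restr[[id]] %||% list(), function(r)
          r[1] == rr$property && filler_below(r[2], rr$filler, closed),
          logical(1)))
      }
      if (ok) tags[[id]] <- c(tags[[id]], rule$tag)
    }
  }
  graph$nodes$tags <- vapply(graph$nodes$id, function(id)
    join_multi(canonical_sort(unique(tags[[id]]))), character(1))
  new_property_graph(graph$nodes, graph$edges)
}

#' Read tag rules from a JSON file
#'
#' Each entry: \code{{"tag": ..., "requires_subclass_of": ...,
#' "requires_restriction": {"property": ..., "filler": ...,
#' "filler_closure": true}}}.
#' @param path JSON file.
#' @export
read_tag_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    tag_rule(r$tag, r$requires_subclass_of %||% NULL,
             r$requires_restriction %||% NULL))
}

#' Emit a property graph to files
#'
#' \code{"tables"} writes \code{nodes.tsv} and \code{edges.tsv} (documented
#' columns; multi-valued cells "|"-separated, residual annotations as a
#' JSON column) which round-trip through \code{\link{read_graph_tables}};
#' \code{"script"} additionally writes \code{graph.cypher} with one
#' creation statement per node and per edge. Output is sorted and
#' byte-deterministic.
#'
#' @param graph property graph.
#' @param dir output directory (created).
#' @param format \code{"tables"} or \code{"script"}.
#' @return paths of the written files, invisibly.
#' @export
emit_graph <- function(graph, dir, format = c("tables", "script")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  np <- file.path(dir, "nodes.tsv"); ep <- file.path(dir, "edges.tsv")
  write_tsv(graph$nodes, np)
  write_tsv(graph$edges, ep)
  out <- c(np, ep)
  if (format == "script") {
    sp <- file.path(dir, "graph.cypher")
    esc <- function(x) gsub("'", "\\\\'", x)
    node_stmts <- sprintf(
      "CREATE (:%s {id: '%s', name: '%s', synonyms: '%s', tags: '%s'});",
      graph$nodes$labels, esc(graph$nodes$id), esc(graph$nodes$name),
      esc(graph$nodes$synonyms), esc(graph$nodes$tags))
    edge_stmts <- sprintf(
      paste0("MATCH (a {id: '%s'}), (b {id: '%s'}) ",
             "CREATE (a)-[:%s {provenance: '%s'}]->(b);"),
      esc(graph$edges$from), esc(graph$edges$to),
      gsub("[^A-Za-z0-9_]", "_", graph$edges$type), esc(graph$edges$provenance))
    write_lines_utf8(c(node_stmts, edge_stmts), sp)
    out <- c(out, sp)
  }
  invisible(out)
}

#' @rdname emit_graph
#' @export
read_graph_tables <- function(dir) {
  nodes <- read_tsv(file.path(dir, "nodes.tsv"))
  edges <- read_tsv(file.path(dir, "edges.tsv"))
  new_property_graph(nodes, edges)
}
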