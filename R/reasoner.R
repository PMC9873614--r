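#' @title Dedicated pattern reasoner
#' @description
#' The schema relies on exactly three entailment patterns, so a dedicated
#' reasoner implements them directly instead of delegating to a general
#' OWL DL engine: (1) the transitive closure of \code{subcluster_of} over
#' cluster individuals; (2) the exemplar property chain — a class defined
#' as \code{cell and has_exemplar value i} is a strict subclass of any
#' class whose exemplar is a strict ancestor of \code{i}, and classes
#' sharing an exemplar are equivalent; (3) EL-style structural subsumption
#' placing generated classes under grouping classes defined by a named
#' conjunct plus existential restrictions. All outputs are sorted by
#' identifier, so reasoning is deterministic.
#' @name reasoner
NULL

## ---- generic digraph helpers (edges as two-column data.frames) ---------

edge_df <- function(from = character(0), to = character(0))
  data.frame(from = as.character(from), to = as.character(to),
             stringsAsFactors = FALSE)

# irreflexive transitive closure of a DAG given as child -> parent edges;
# hard error naming a cycle if one exists
closure_pairs <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  up <- split(edges$to, factor(edges$from, levels = nodes))
  memo <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  anc <- function(n) {
    if (!is.null(memo[[n]])) return(memo[[n]])
    if (isTRUE(state[[n]]))
      stop_ccn("CYCLE", "cycle detected through '%s'", n)
    state[[n]] <- TRUE
    out <- character(0)
    for (p in up[[n]] %||% character(0)) out <- c(out, p, anc(p))
    out <- unique(out)
    if (n %in% out) stop_ccn("CYCLE", "cycle detected through '%s'", n)
    state[[n]] <- FALSE
    memo[[n]] <- out
    out
  }
  res <- lapply(stats::setNames(nodes, nodes), anc)
  lens <- lengths(res)
  out <- edge_df(rep(names(res), lens), unlist(res, use.names = FALSE))
  out[canonical_order(paste(out$from, out$to)), , drop = FALSE]
}

# reflexive reachability test helper: named list id -> ancestor set
ancestor_sets <- function(edges) {
  cl <- closure_pairs(edges)
  split(cl$to, factor(cl$from, levels = unique(c(edges$from, edges$to))))
}

#' Transitive closure of the subcluster relation
#'
#' Returns every (descendant, ancestor) pair entailed by the direct parent
#' links: for an ontology document, over \code{subcluster_of} assertions
#' between cluster individuals; for a taxonomy, over accessions.
#'
#' @param x an \code{\link{ontology_document}}, a \code{\link{taxonomy}},
#'   or a list of taxonomies (accessions must not collide).
#' @param config build configuration (for the relation identifier).
#' @return data.frame with columns \code{descendant}, \code{ancestor}.
#' @export
subcluster_closure <- function(x, config = default_config()) {
  if (inherits(x, "ontology_document")) {
    v <- config$vocabulary
    ax <- axioms_of_type(x, "ObjectPropertyAssertion")
    ax <- ax[vapply(ax, function(a) a$property == v$subcluster_of, logical(1))]
    edges <- edge_df(vapply(ax, `[[`, character(1), "subject"),
                     vapply(ax, `[[`, character(1), "object"))
  } else {
    txs <- if (inherits(x, "ccn_taxonomy")) list(x) else x
    acc <- unlist(lapply(txs, taxonomy_accessions))
    if (anyDuplicated(acc))
      stop_ccn("DUP_ACCESSION",
               "accessions collide across taxonomies; reason per taxonomy or on the ontology")
    parents <- do.call(c, lapply(txs, taxonomy_parents))
    keep <- !is.na(parents)
    edges <- edge_df(names(parents)[keep], unname(parents[keep]))
  }
  cl <- closure_pairs(edges)
  stats::setNames(cl, c("descendant", "ancestor"))
}

## ---- inferred hierarchy container --------------------------------------

#' Inferred class hierarchy
#'
#' Strict-subclass pairs with a provenance tag (\code{"data-driven"},
#' \code{"structural"} or \code{"asserted"}) plus disjoint equivalence
#' groups (classes sharing an exemplar are reported equivalent, not
#' collapsed, so modelling errors stay visible). The pair set must be a
#' DAG.
#'
#' @param pairs data.frame with columns \code{sub}, \code{sup},
#'   \code{provenance}.
#' @param equivalences list of character vectors of class ids.
#' @export
inferred_hierarchy <- function(pairs = NULL, equivalences = list()) {
  if (is.null(pairs))
    pairs <- data.frame(sub = character(0), sup = character(0),
                        provenance = character(0), stringsAsFactors = FALSE)
  pairs <- unique(pairs[, c("sub", "sup", "provenance")])
  if (any(pairs$sub == pairs$sup))
    stop_ccn("REFLEXIVE_PAIR", "strict-subclass pairs must be irreflexive")
  closure_pairs(edge_df(pairs$sub, pairs$sup))  # errors on a cycle
  if (length(equivalences) > 1L &&
      anyDuplicated(unlist(equivalences)))
    stop_ccn("EQUIV_OVERLAP", "equivalence groups must be disjoint")
  pairs <- pairs[canonical_order(paste(pairs$sub, pairs$sup, pairs$provenance)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 equivalences = equivalences[canonical_order(
                   vapply(equivalences, function(g) canonical_sort(g)[1],
                          character(1)) %||% character(0))]),
            class = "inferred_hierarchy")
}

#' @export
print.inferred_hierarchy <- function(x, ...) {
  cat(sprintf("<inferred_hierarchy> %d strict-subclass pairs (%s), %d equivalence group(s)\n",
              nrow(x$pairs),
              paste(sprintf("%d %s", table(x$pairs$provenance),
                            names(table(x$pairs$provenance))), collapse = ", "),
              length(x$equivalences)))
  invisible(x)
}

# exemplar map from equivalence axioms: class id -> exemplar individual
exemplar_map <- function(doc, config = default_config()) {
  v <- config$vocabulary
  eqs <- axioms_of_type(doc, "EquivalentClasses")
  out <- character(0)
  for (ax in eqs) {
    e <- ax$expr
    if (e$type != "And") next
    vals <- Filter(function(a) a$type == "Value" &&
                     a$property == v$has_exemplar, e$args)
    if (length(vals) == 1L) out[ax$id] <- vals[[1]]$individual
  }
  out
}

#' Data-driven classification via the exemplar chain
#'
#' Class A is inferred a strict subclass of class B iff A's exemplar is a
#' strict descendant of B's exemplar in the subcluster closure; classes
#' with the same exemplar are inferred equivalent. This reproduces, at the
#' class level, exactly the entailments the exemplar property chain
#' licenses in OWL.
#'
#' @param exemplars named character vector class id -> exemplar individual,
#'   or an \code{\link{ontology_document}} to extract it from.
#' @param closure data.frame from \code{\link{subcluster_closure}}.
#' @param reduce return only the transitive reduction of the inferred
#'   pairs (default); \code{FALSE} returns the full closure.
#' @return an \code{\link{inferred_hierarchy}} with provenance
#'   \code{"data-driven"}.
#' @export
classify_data_driven <- function(exemplars, closure,
                                 config = default_config(), reduce = TRUE) {
  if (inherits(exemplars, "ontology_document"))
    exemplars <- exemplar_map(exemplars, config)
  anc <- split(closure$ancestor, factor(closure$descendant,
                                        levels = unique(c(closure$descendant,
                                                          closure$ancestor))))
  classes <- names(exemplars)
  by_ex <- split(classes, exemplars[classes])
  pairs <- edge_df()
  for (a in classes) {
    above <- anc[[exemplars[[a]]]] %||% character(0)
    sups <- classes[exemplars[classes] %in% above]
    if (length(sups))
      pairs <- rbind(pairs, edge_df(a, sups))
  }
  equiv <- unname(Filter(function(g) length(g) > 1L, by_ex))
  pairs <- data.frame(sub = pairs$from, sup = pairs$to,
                      provenance = rep("data-driven", nrow(pairs)),
                      stringsAsFactors = FALSE)
  h <- inferred_hierarchy(pairs, equiv)
  if (reduce) transitive_reduction(h) else h
}

#' Structural placement under grouping classes
#'
#' A generated class G is placed under a grouping class D (defined as one
#' named class plus existential-restriction conjuncts) iff some asserted
#' named superclass of G reaches D's named conjunct through the subclass
#' closure, and every restriction conjunct \code{R some F} of D is matched
#' by an asserted restriction \code{R' some F'} on G with R' a subproperty
#' of (or equal to) R and F' a subclass of (or equal to) F.
#'
#' @param doc ontology document carrying the asserted axioms of the
#'   generated classes.
#' @param stub imports-stub data.frame (see
#'   \code{\link{parse_imports_stub}}); rows with definition conjuncts are
#'   the grouping classes.
#' @param candidates class ids to try to place; defaults to the classes
#'   with an exemplar equivalence axiom.
#' @return an \code{\link{inferred_hierarchy}} with provenance
#'   \code{"structural"}.
#' @export
classify_structural <- function(doc, stub, candidates = NULL,
                                config = default_config()) {
  if (is.null(candidates)) candidates <- names(exemplar_map(doc, config))
  sub_ax <- axioms_of_type(doc, "SubClassOf")
  named_sup <- list(); restr <- list()
  for (ax in sub_ax) {
    if (ax$sup$type == "Class") {
      named_sup[[ax$sub]] <- c(named_sup[[ax$sub]], ax$sup$id)
    } else if (ax$sup$type == "Some" && ax$sup$filler$type == "Class") {
      restr[[ax$sub]] <- c(restr[[ax$sub]],
                           list(c(ax$sup$property, ax$sup$filler$id)))
    }
  }
  # class closure: stub parents plus asserted named-named subclass axioms
  cls_edges <- edge_df()
  stub_cls <- stub[stub$kind == "class", , drop = FALSE]
  keep <- nzchar(stub_cls$parent)
  cls_edges <- rbind(cls_edges, edge_df(stub_cls$id[keep], stub_cls$parent[keep]))
  for (s in names(named_sup))
    cls_edges <- rbind(cls_edges, edge_df(s, named_sup[[s]]))
  cls_anc <- ancestor_sets(unique(cls_edges))
  reaches <- function(a, b) a == b || b %in% (cls_anc[[a]] %||% character(0))
  # property closure from stub subproperty links
  stub_prp <- stub[stub$kind == "object_property", , drop = FALSE]
  keep <- nzchar(stub_prp$parent)
  prp_anc <- if (any(keep))
    ancestor_sets(edge_df(stub_prp$id[keep], stub_prp$parent[keep]))
  else list()
  prop_under <- function(a, b) a == b || b %in% (prp_anc[[a]] %||% character(0))

  groupings <- stub[stub$kind == "class" &
                      lengths(stub$conjuncts) > 0L, , drop = FALSE]
  pairs <- edge_df()
  for (i in seq_len(nrow(groupings))) {
    did <- groupings$id[i]
    conj <- groupings$conjuncts[[i]]
    named <- Filter(function(cj) cj$type == "named", conj)
    some <- Filter(function(cj) cj$type == "some", conj)
    if (length(named) != 1L)
      stop_ccn("BAD_DEFINITION",
               "grouping class %s must have exactly one named conjunct", did)
    for (g in candidates) {
      if (g == did) next
      ok <- any(vapply(named_sup[[g]] %||% character(0),
                       reaches, logical(1), b = named[[1]]$id))
      if (ok) for (cj in some) {
        hit <- any(vapply(restr[[g]] %||% list(), function(r)
          prop_under(r[1], cj$property) && reaches(r[2], cj$filler),
          logical(1)))
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) pairs <- rbind(pairs, edge_df(g, did))
    }
  }
  inferred_hierarchy(data.frame(sub = pairs$from, sup = pairs$to,
                                provenance = rep("structural", nrow(pairs)),
                                stringsAsFactors = FALSE))
}

#' Transitive closure / reduction of an inferred hierarchy
#'
#' The reduction keeps the minimal edge set with the same closure (unique
#' for a DAG); provenance of a surviving closure pair is taken from the
#' original pair when present. Reduction is idempotent.
#'
#' @param h an \code{\link{inferred_hierarchy}} (or a pairs data.frame).
#' @export
transitive_reduction <- function(h) {
  pairs <- if (inherits(h, "inferred_hierarchy")) h$pairs else h
  cl <- closure_pairs(edge_df(pairs$sub, pairs$sup))
  clk <- paste(cl$from, cl$to)
  anc <- split(cl$to, factor(cl$from, levels = unique(c(cl$from, cl$to))))
  redundant <- vapply(seq_len(nrow(cl)), function(i) {
    mids <- anc[[cl$from[i]]]
    any(vapply(setdiff(mids, cl$to[i]), function(m)
      cl$to[i] %in% (anc[[m]] %||% character(0)), logical(1)))
  }, logical(1))
  keep <- cl[!redundant, , drop = FALSE]
  prov <- stats::setNames(pairs$provenance, paste(pairs$sub, pairs$sup))
  out <- data.frame(sub = keep$from, sup = keep$to,
                    provenance = unname(prov[paste(keep$from, keep$to)]),
                    stringsAsFactors = FALSE)
  out$provenance[is.na(out$provenance)] <- "data-driven"
  if (inherits(h, "inferred_hierarchy"))
    inferred_hierarchy(out, h$equivalences)
  else inferred_hierarchy(out)
}

#' Full transitive closure of an inferred hierarchy
#' @rdname transitive_reduction
#' @export
hierarchy_closure <- function(h) {
  pairs <- if (inherits(h, "inferred_hierarchy")) h$pairs else h
  cl <- closure_pairs(edge_df(pairs$sub, pairs$sup))
  prov <- stats::setNames(pairs$provenance, paste(pairs$sub, pairs$sup))
  out <- data.frame(sub = cl$from, sup = cl$to,
                    provenance = unname(prov[paste(cl$from, cl$to)]),
                    stringsAsFactors = FALSE)
  out$provenance[is.na(out$provenance)] <- "data-driven"
  inferred_hierarchy(out, if (inherits(h, "inferred_hierarchy"))
    h$equivalences else list())
}

#' Run the full reasoning stage over a built ontology
#'
#' Combines asserted named-class subsumptions, data-driven classification
#' via the exemplar chain, and structural placement under grouping classes,
#' then transitively reduces the union. Provenance tags survive into the
#' property-graph projection.
#'
#' @param doc merged ontology document.
#' @param stub imports stub (may be NULL: no structural stage).
#' @param config build configuration.
#' @return an \code{\link{inferred_hierarchy}}.
#' @export
reason_ontology <- function(doc, stub = NULL, config = default_config()) {
  closure <- subcluster_closure(doc, config)
  dd <- classify_data_driven(doc, closure, config, reduce = FALSE)
  v <- config$vocabulary
  classes <- doc$entities$id[doc$entities$kind == "class"]
  asserted <- edge_df()
  for (ax in axioms_of_type(doc, "SubClassOf"))
    if (ax$sup$type == "Class" &&
        ax$sup$id != v$cell)  # cell membership is carried by the equivalence
      asserted <- rbind(asserted, edge_df(ax$sub, ax$sup$id))
  # homology renderings are cross-links, not is-a: they are existential
  # restrictions and thus never enter `asserted`
  pairs <- rbind(dd$pairs,
                 data.frame(sub = asserted$from, sup = asserted$to,
                            provenance = rep("asserted", nrow(asserted)),
                            stringsAsFactors = FALSE))
  if (!is.null(stub) && nrow(stub)) {
    st <- classify_structural(doc, stub, config = config)
    pairs <- rbind(pairs, st$pairs)
  }
  pairs <- unique(pairs)
  # keep the strongest provenance when a pair is derivable several ways
  ord <- c(asserted = 1L, `data-driven` = 2L, structural = 3L)
  pairs <- pairs[order(paste(pairs$sub, pairs$sup), ord[pairs$provenance]), ,
                 drop = FALSE]
  pairs <- pairs[!duplicated(paste(pairs$sub, pairs$sup)), , drop = FALSE]
  transitive_reduction(inferred_hierarchy(pairs, dd$equivalences))
}

#' Merge inferred subclass pairs back into the ontology
#'
#' Adds each inferred pair as a SubClassOf axiom; pairs not already
#' asserted are tagged with an \code{inferred} annotation on the subclass.
#'
#' @param doc ontology document.
#' @param h inferred hierarchy.
#' @export
merge_inferred <- function(doc, h, config = default_config()) {
  v <- config$vocabulary
  axs <- list()
  for (i in seq_len(nrow(h$pairs))) {
    axs <- c(axs, list(ax_subclass(h$pairs$sub[i], ce_class(h$pairs$sup[i]))))
    if (h$pairs$provenance[i] != "asserted")
      axs <- c(axs, list(ax_annotation(
        v$inferred, h$pairs$sub[i],
        sprintf("%s subClassOf %s [%s]", h$pairs$sub[i], h$pairs$sup[i],
                h$pairs$provenance[i]))))
  }
  add_axioms(doc, axs)
}
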