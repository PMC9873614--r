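#' @title Readers and writers for the CCN-style input dialects
#' @description
#' The pipeline ingests: a dendrogram document (nested JSON nodes carrying
#' accessions and heights), a nomenclature table (one row per cluster:
#' aliases, class flag, arbitrary retained metadata columns), NS-Forest
#' marker tables, curated class-annotation tables, cross-taxonomy homology
#' tables, reference gene lists and an imports stub supplying external
#' grouping classes. All tables are tab-separated UTF-8 with a header row;
#' column names are configurable through a mapping and default to the CCN
#' convention. Every reader with a writer round-trips exactly on the
#' canonical dialect, and no input cell is silently dropped: each is either
#' mapped to a typed field or preserved verbatim in node metadata.
#' @name ccn-io
NULL

default_column_map <- function() {
  list(
    accession = "cell_set_accession",
    preferred_alias = "cell_set_preferred_alias",
    aligned_alias = "cell_set_aligned_alias",
    additional_aliases = "cell_set_additional_aliases",
    class_flag = "cell_set_class_flag",
    markers = "markers",
    fbeta = "f_beta",
    method = "method",
    parent_classes = "parent_class_ids",
    morphology = "morphology_term",
    projection = "projection_term",
    classical_markers = "classical_marker_genes",
    extra_synonyms = "extra_synonyms",
    exclude = "exclude",
    group_id = "homology_group",
    taxonomy_id = "taxonomy_id",
    gene_id = "identifier",
    gene_symbol = "symbol"
  )
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    quote = "", fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  write_lines_utf8(lines, path)
}

parse_bool <- function(x) tolower(trimws(x)) %in% c("true", "t", "1", "yes", "y")

## ---- dendrogram --------------------------------------------------------

#' Parse a dendrogram document into a taxonomy skeleton
#'
#' The dendrogram is a nested JSON document: each node carries an
#' \code{accession}, an optional \code{height} (retained as the division
#' confidence measure), an optional list of \code{children}, and any other
#' attributes (display order, colours) which are preserved as node metadata.
#'
#' @param path path to the dendrogram JSON file.
#' @param taxonomy_id,species,brain_region,is_anchor taxonomy-level fields
#'   (the dendrogram itself may carry them at top level; arguments override).
#' @return a \code{\link{taxonomy}}.
#' @export
parse_dendrogram <- function(path, taxonomy_id = NULL, species = NULL,
                             brain_region = NULL, is_anchor = NULL) {
  docu <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                   error = function(e)
                     stop_ccn("PARSE_ERROR", "malformed dendrogram %s: %s",
                              path, conditionMessage(e)))
  roots <- if (!is.null(docu$nodes)) docu$nodes else list(docu$root %||% docu)
  nodes <- list()
  walk <- function(node, parent) {
    acc <- node$accession
    if (is.null(acc) || !nzchar(acc))
      stop_ccn("PARSE_ERROR", "dendrogram node without accession in %s", path)
    meta <- node[setdiff(names(node), c("accession", "height", "children"))]
    nodes[[length(nodes) + 1L]] <<- cluster_node(
      accession = acc, parent_accession = parent,
      confidence = as.numeric(node$height %||% NA_real_),
      metadata = lapply(meta, as.character))
    for (ch in node$children %||% list()) walk(ch, acc)
  }
  for (r in roots) walk(r, NA_character_)
  acc <- vapply(nodes, `[[`, character(1), "accession")
  if (anyDuplicated(acc))
    stop_ccn("DUP_ACCESSION", "duplicate accession(s) in dendrogram %s: %s",
             path, paste(unique(acc[duplicated(acc)]), collapse = ", "))
  taxonomy(
    taxonomy_id = taxonomy_id %||% docu$taxonomy_id %||% "taxonomy",
    species = species %||% docu$species %||% NA_character_,
    brain_region = brain_region %||% docu$brain_region %||% NA_character_,
    nodes = nodes,
    is_anchor = is_anchor %||% isTRUE(docu$is_anchor))
}

#' Write a taxonomy back to the canonical dendrogram JSON dialect
#' @param tx taxonomy.
#' @param path output path.
#' @export
write_dendrogram <- function(tx, path) {
  parents <- taxonomy_parents(tx)
  by_acc <- stats::setNames(tx$nodes, names(parents))
  children <- split(names(parents), factor(parents, levels = names(parents)))
  emit <- function(acc) {
    nd <- by_acc[[acc]]
    out <- list(accession = acc)
    if (!is.na(nd$confidence)) out$height <- nd$confidence
    out <- c(out, nd$metadata)
    kids <- canonical_sort(children[[acc]] %||% character(0))
    if (length(kids)) out$children <- lapply(kids, emit)
    out
  }
  roots <- canonical_sort(names(parents)[is.na(parents)])
  docu <- list(taxonomy_id = tx$taxonomy_id, species = tx$species,
               brain_region = tx$brain_region, is_anchor = tx$is_anchor,
               nodes = lapply(roots, emit))
  write_lines_utf8(jsonlite::toJSON(docu, auto_unbox = TRUE, pretty = TRUE,
                                    digits = NA, null = "null"), path)
}

## ---- nomenclature ------------------------------------------------------

#' Parse a nomenclature table and fold it into a taxonomy
#'
#' Recognised columns (per the column map) populate the typed node fields:
#' preferred/aligned/additional aliases and the class-generation flag. Every
#' unrecognised column is preserved verbatim in node metadata, so the
#' original file content round-trips into ontology annotations.
#'
#' @param path TSV path.
#' @param tx taxonomy skeleton from \code{\link{parse_dendrogram}}; may be
#'   \code{NULL} to get bare records.
#' @param columns column-name map (see defaults in the package config).
#' @param config build configuration (alias delimiter).
#' @return the taxonomy with node fields filled in (or a list of records if
#'   \code{tx} is NULL).
#' @export
parse_nomenclature_table <- function(path, tx = NULL,
                                     columns = default_column_map(),
                                     config = default_config()) {
  tab <- read_tsv(path)
  if (!(columns$accession %in% names(tab)))
    stop_ccn("MISSING_COLUMN", "nomenclature table %s lacks accession column '%s'",
             path, columns$accession)
  known <- unlist(columns[c("accession", "preferred_alias", "aligned_alias",
                            "additional_aliases", "class_flag")])
  records <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, , drop = FALSE]
    extra <- setdiff(names(tab), known)
    list(accession = row[[columns$accession]],
         preferred_alias = if (columns$preferred_alias %in% names(tab))
           row[[columns$preferred_alias]] else "",
         aligned_alias = if (columns$aligned_alias %in% names(tab))
           row[[columns$aligned_alias]] else "",
         additional_aliases = if (columns$additional_aliases %in% names(tab))
           split_multi(row[[columns$additional_aliases]],
                       config$alias_delimiter) else character(0),
         flagged_for_class = if (columns$class_flag %in% names(tab))
           parse_bool(row[[columns$class_flag]]) else FALSE,
         metadata = stats::setNames(as.list(as.character(row[extra])), extra))
  })
  if (is.null(tx)) return(records)
  acc <- taxonomy_accessions(tx)
  idx <- stats::setNames(seq_along(acc), acc)
  for (rec in records) {
    if (!(rec$accession %in% acc))
      stop_ccn("UNKNOWN_ACCESSION",
               "nomenclature row for %s has no dendrogram node", rec$accession)
    i <- idx[[rec$accession]]
    nd <- tx$nodes[[i]]
    nd$preferred_alias <- rec$preferred_alias
    nd$aligned_alias <- rec$aligned_alias
    nd$additional_aliases <- rec$additional_aliases
    nd$flagged_for_class <- rec$flagged_for_class
    nd$metadata <- c(nd$metadata, rec$metadata)
    tx$nodes[[i]] <- nd
  }
  tx
}

#' Write the nomenclature table for a taxonomy (canonical dialect)
#' @export
#' @rdname parse_nomenclature_table
write_nomenclature_table <- function(tx, path, columns = default_column_map(),
                                     config = default_config()) {
  meta_keys <- canonical_sort(unique(unlist(lapply(tx$nodes, function(n)
    names(n$metadata)))))
  rows <- lapply(tx$nodes, function(n) {
    base <- stats::setNames(
      list(n$accession, n$preferred_alias, n$aligned_alias,
           join_multi(n$additional_aliases, config$alias_delimiter),
           tolower(as.character(n$flagged_for_class))),
      unlist(columns[c("accession", "preferred_alias", "aligned_alias",
                       "additional_aliases", "class_flag")]))
    meta <- stats::setNames(
      lapply(meta_keys, function(k) as.character(n$metadata[[k]] %||% "")),
      meta_keys)
    as.data.frame(c(base, meta), check.names = FALSE,
                  stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[canonical_order(df[[columns$accession]]), , drop = FALSE]
  write_tsv(df, path)
}

## ---- gene lists and markers --------------------------------------------

#' Parse a reference gene list (identifier, symbol)
#' @param path two-column TSV.
#' @export
parse_gene_list <- function(path, columns = default_column_map()) {
  tab <- read_tsv(path)
  for (cn in c(columns$gene_id, columns$gene_symbol))
    if (!(cn %in% names(tab)))
      stop_ccn("MISSING_COLUMN", "gene list %s lacks column '%s'", path, cn)
  data.frame(identifier = tab[[columns$gene_id]],
             symbol = tab[[columns$gene_symbol]], stringsAsFactors = FALSE)
}

#' @rdname parse_gene_list
#' @export
write_gene_list <- function(genes, path, columns = default_column_map()) {
  df <- stats::setNames(genes[, c("identifier", "symbol")],
                        c(columns$gene_id, columns$gene_symbol))
  write_tsv(df[canonical_order(df[[1]]), , drop = FALSE], path)
}

#' Parse an NS-Forest marker table
#'
#' One row per cluster: accession, a delimited list of marker gene symbols,
#' and the F-beta score of the marker-based classifier. Symbols are resolved
#' to identifiers against the reference gene list; resolution is
#' case-sensitive unless \code{config$gene_match_case_insensitive}.
#'
#' @param path TSV path.
#' @param gene_list data.frame from \code{\link{parse_gene_list}}.
#' @param strict unresolvable symbol: error (TRUE) or drop with a report
#'   entry (FALSE).
#' @return list with \code{marker_sets} (list of \code{\link{marker_set}})
#'   and \code{report} (violations found while parsing).
#' @export
parse_marker_table <- function(path, gene_list, columns = default_column_map(),
                               config = default_config(),
                               strict = config$strict) {
  tab <- read_tsv(path)
  for (cn in c(columns$accession, columns$markers, columns$fbeta))
    if (!(cn %in% names(tab)))
      stop_ccn("MISSING_COLUMN", "marker table %s lacks column '%s'", path, cn)
  sym <- gene_list$symbol
  if (config$gene_match_case_insensitive) sym <- tolower(sym)
  lookup <- stats::setNames(gene_list$identifier, sym)
  report <- new_report()
  sets <- list()
  for (i in seq_len(nrow(tab))) {
    acc <- tab[[columns$accession]][i]
    raw <- split_multi(tab[[columns$markers]][i], ",")
    if (length(raw) == 0L)
      stop_ccn("EMPTY_MARKERS", "marker row %d (%s) has no genes", i, acc)
    keys <- if (config$gene_match_case_insensitive) tolower(raw) else raw
    hit <- keys %in% names(lookup)
    if (any(!hit)) {
      msg <- sprintf("unresolvable gene symbol(s): %s",
                     paste(raw[!hit], collapse = ", "))
      if (strict) stop_ccn("UNKNOWN_GENE", "%s (cluster %s)", msg, acc)
      report <- add_finding(report, "UNKNOWN_GENE", acc, msg, "WARNING")
    }
    fb <- suppressWarnings(as.numeric(tab[[columns$fbeta]][i]))
    if (is.na(fb) || fb < 0 || fb > 1)
      stop_ccn("FBETA_RANGE", "fbeta '%s' outside [0,1] for %s",
               tab[[columns$fbeta]][i], acc)
    genes <- unname(lookup[keys[hit]])
    if (length(genes) == 0L)
      stop_ccn("EMPTY_MARKERS", "no resolvable genes for cluster %s", acc)
    method <- if (columns$method %in% names(tab)) tab[[columns$method]][i]
              else "NS-Forest"
    sets[[length(sets) + 1L]] <- marker_set(acc, genes, fb, method)
  }
  list(marker_sets = sets, report = report)
}

#' @rdname parse_marker_table
#' @export
write_marker_table <- function(marker_sets, gene_list, path,
                               columns = default_column_map()) {
  sym <- stats::setNames(gene_list$symbol, gene_list$identifier)
  df <- do.call(rbind, lapply(marker_sets, function(ms)
    data.frame(a = ms$cluster_accession,
               m = paste(sym[ms$genes], collapse = ","),
               f = format_shortest(ms$fbeta), mt = ms$method,
               stringsAsFactors = FALSE)))
  names(df) <- unlist(columns[c("accession", "markers", "fbeta", "method")])
  write_tsv(df[canonical_order(df[[1]]), , drop = FALSE], path)
}

## ---- curation ----------------------------------------------------------

#' Parse a curated class-annotation table
#'
#' @return list with \code{records} (list of
#'   \code{\link{curated_class_record}}) and \code{report}.
#' @export
parse_curation_table <- function(path, columns = default_column_map(),
                                 config = default_config()) {
  tab <- read_tsv(path)
  if (!(columns$accession %in% names(tab)))
    stop_ccn("MISSING_COLUMN", "curation table %s lacks accession column", path)
  report <- new_report()
  get <- function(i, key, default = "") {
    cn <- columns[[key]]
    if (cn %in% names(tab)) tab[[cn]][i] else default
  }
  records <- lapply(seq_len(nrow(tab)), function(i) {
    acc <- tab[[columns$accession]][i]
    terms <- c(split_multi(get(i, "parent_classes"), config$alias_delimiter),
               morph = get(i, "morphology"), proj = get(i, "projection"))
    bad <- terms[nzchar(terms) & !is_curie(terms)]
    if (length(bad))
      report <<- add_finding(report, "BAD_TERM_ID", acc,
                             sprintf("malformed term identifier(s): %s",
                                     paste(bad, collapse = ", ")))
    curated_class_record(
      cluster_accession = acc,
      parent_class_ids = split_multi(get(i, "parent_classes"),
                                     config$alias_delimiter),
      morphology_term = if (nzchar(get(i, "morphology"))) get(i, "morphology")
                        else NA_character_,
      projection_term = if (nzchar(get(i, "projection"))) get(i, "projection")
                        else NA_character_,
      classical_marker_genes = split_multi(get(i, "classical_markers"),
                                           config$alias_delimiter),
      extra_synonyms = split_multi(get(i, "extra_synonyms"),
                                   config$alias_delimiter),
      exclude = parse_bool(get(i, "exclude", "false")))
  })
  list(records = records, report = report)
}

#' @rdname parse_curation_table
#' @export
write_curation_table <- function(records, path, columns = default_column_map(),
                                 config = default_config()) {
  d <- config$alias_delimiter
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(a = r$cluster_accession,
               p = join_multi(r$parent_class_ids, d),
               m = if (is.na(r$morphology_term)) "" else r$morphology_term,
               j = if (is.na(r$projection_term)) "" else r$projection_term,
               c = join_multi(r$classical_marker_genes, d),
               s = join_multi(r$extra_synonyms, d),
               e = tolower(as.character(r$exclude)),
               stringsAsFactors = FALSE)))
  names(df) <- unlist(columns[c("accession", "parent_classes", "morphology",
                                "projection", "classical_markers",
                                "extra_synonyms", "exclude")])
  write_tsv(df[canonical_order(df[[1]]), , drop = FALSE], path)
}

## ---- homology ----------------------------------------------------------

#' Parse a cross-taxonomy homology table
#'
#' Rows associate a group id with (taxonomy, accession) members; groups are
#' assembled across rows. Singleton groups carry no cross-species
#' information and are dropped with a report entry.
#'
#' @return list with \code{groups} (list of \code{\link{homology_group}})
#'   and \code{report}.
#' @export
parse_homology_table <- function(path, columns = default_column_map()) {
  tab <- read_tsv(path)
  for (cn in c(columns$group_id, columns$taxonomy_id, columns$accession))
    if (!(cn %in% names(tab)))
      stop_ccn("MISSING_COLUMN", "homology table %s lacks column '%s'", path, cn)
  report <- new_report()
  groups <- list()
  for (gid in canonical_sort(unique(tab[[columns$group_id]]))) {
    rows <- tab[tab[[columns$group_id]] == gid, , drop = FALSE]
    if (nrow(rows) < 2L) {
      report <- add_finding(report, "SINGLETON_HOMOLOGY", gid,
                            "homology group with a single member dropped",
                            "WARNING")
      next
    }
    groups[[length(groups) + 1L]] <- homology_group(
      gid, data.frame(taxonomy_id = rows[[columns$taxonomy_id]],
                      cluster_accession = rows[[columns$accession]],
                      stringsAsFactors = FALSE))
  }
  list(groups = groups, report = report)
}

#' @rdname parse_homology_table
#' @export
write_homology_table <- function(groups, path, columns = default_column_map()) {
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(g = g$group_id, t = g$members$taxonomy_id,
               a = g$members$cluster_accession, stringsAsFactors = FALSE)))
  names(df) <- unlist(columns[c("group_id", "taxonomy_id", "accession")])
  df <- df[canonical_order(paste(df[[1]], df[[2]], df[[3]])), , drop = FALSE]
  write_tsv(df, path)
}

## ---- datasets ----------------------------------------------------------

#' Parse a dataset table (dataset_id, taxonomy_id, source_url, title)
#' @param path TSV path.
#' @export
parse_dataset_table <- function(path) {
  tab <- read_tsv(path)
  for (cn in c("dataset_id", "taxonomy_id", "source_url"))
    if (!(cn %in% names(tab)))
      stop_ccn("MISSING_COLUMN", "dataset table %s lacks column '%s'", path, cn)
  lapply(seq_len(nrow(tab)), function(i)
    dataset_record(tab$dataset_id[i], tab$taxonomy_id[i], tab$source_url[i],
                   if ("title" %in% names(tab)) tab$title[i] else ""))
}

#' @rdname parse_dataset_table
#' @export
write_dataset_table <- function(datasets, path) {
  df <- do.call(rbind, lapply(datasets, function(d)
    data.frame(dataset_id = d$dataset_id, taxonomy_id = d$taxonomy_id,
               source_url = d$source_url, title = d$title,
               stringsAsFactors = FALSE)))
  write_tsv(df[canonical_order(df$dataset_id), , drop = FALSE], path)
}

## ---- imports stub ------------------------------------------------------

#' Parse an imports stub table
#'
#' External grouping classes and context terms are supplied as a small
#' self-contained table so builds need no network imports: columns
#' \code{id}, \code{label}, \code{kind} (class/object_property),
#' \code{parent} (subclass/subproperty parent id) and
#' \code{definition_conjuncts} — for grouping classes, a "|"-separated list
#' whose first element is a named class and whose remaining elements are
#' existential restrictions written \code{"<property> some <filler>"}.
#'
#' @param path TSV path.
#' @return data.frame with list-column \code{conjuncts}.
#' @export
parse_imports_stub <- function(path, config = default_config()) {
  tab <- read_tsv(path)
  for (cn in c("id", "label"))
    if (!(cn %in% names(tab)))
      stop_ccn("MISSING_COLUMN", "imports stub %s lacks column '%s'", path, cn)
  tab$kind <- if ("kind" %in% names(tab)) tab$kind else "class"
  tab$parent <- if ("parent" %in% names(tab)) tab$parent else ""
  defs <- if ("definition_conjuncts" %in% names(tab))
    tab$definition_conjuncts else rep("", nrow(tab))
  tab$conjuncts <- lapply(defs, function(d)
    lapply(split_multi(d, config$alias_delimiter), parse_conjunct))
  tab
}

parse_conjunct <- function(s) {
  m <- regmatches(s, regexec("^(\\S+)\\s+some\\s+(\\S+)$", s))[[1]]
  if (length(m) == 3L)
    list(type = "some", property = m[2], filler = m[3])
  else if (is_curie(s))
    list(type = "named", id = s)
  else stop_ccn("BAD_CONJUNCT", "cannot parse definition conjunct '%s'", s)
}
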