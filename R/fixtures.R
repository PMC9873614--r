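#' @title Synthetic-fixture generator
#' @description
#' Generates complete, mutually consistent input bundles — dendrograms,
#' nomenclature tables, marker tables, gene lists, curation, homology,
#' imports stub, datasets — in exactly the dialects the readers consume,
#' together with a ground-truth record that makes every count-based test
#' oracle exact rather than statistical. A single integer seed drives one
#' generator stream, so every fixture is byte-reproducible. The generator
#' emulates the shape of real taxonomy releases (tree topology, strictly
#' leafward-decreasing dendrogram heights, flagged intermediate nodes,
#' cross-species alias transfer); it does not simulate expression matrices
#' or realistic transcriptomic statistics.
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

rand_alias <- function(n) {
  con <- c("b", "c", "d", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  base <- vapply(seq_len(n), function(i) {
    k <- sample(2:3, 1)
    s <- paste0(sample(con, k, TRUE), sample(vow, k, TRUE), collapse = "")
    paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  }, character(1))
  make.unique(base, sep = "")
}

#' Generate a random taxonomy with its input files
#'
#' Builds a random tree with exactly \code{n_leaves} leaves and depth at
#' most \code{max_depth} (at most 4 children per node), heights strictly
#' decreasing leafward so they are a valid division-confidence measure,
#' and internal nodes flagged for class generation with probability
#' \code{flag_fraction}. When \code{dir} is given, the dendrogram JSON and
#' nomenclature TSV are written there.
#'
#' @param seed integer seed.
#' @param n_leaves number of leaf clusters (>= 1).
#' @param max_depth maximum depth in edges (>= 1).
#' @param flag_fraction probability an internal node is flagged.
#' @param species,brain_region term CURIEs.
#' @param taxonomy_id taxonomy identifier.
#' @param is_anchor anchor-species taxonomy?
#' @param aligned_from optional character pool of anchor aliases; non-anchor
#'   nodes draw an aligned alias from it with probability 1/2.
#' @param dir optional output directory.
#' @return list: \code{taxonomy}, \code{ground_truth}, \code{files}.
#' @export
generate_taxonomy <- function(seed, n_leaves, max_depth = 4L,
                              flag_fraction = 0.5,
                              species = "NCBITaxon:10090",
                              brain_region = "UBERON:0001384",
                              taxonomy_id = "TX01", is_anchor = TRUE,
                              aligned_from = NULL, dir = NULL) {
  stopifnot(n_leaves >= 1L, max_depth >= 1L,
            flag_fraction >= 0, flag_fraction <= 1)
  if (n_leaves > 4^max_depth)
    stop_ccn("SHAPE", "%d leaves do not fit in depth %d with branching 4",
             n_leaves, max_depth)
  with_seed(seed, {
    counter <- 0L
    next_acc <- function() {
      counter <<- counter + 1L
      sprintf("%s_%04d", taxonomy_id, counter)
    }
    nodes <- list()
    grow <- function(n, depth_left, parent, height) {
      acc <- next_acc()
      is_leaf <- n == 1L
      nodes[[length(nodes) + 1L]] <<- list(
        accession = acc, parent = parent, height = height, leaf = is_leaf)
      if (is_leaf) return(invisible(acc))
      cap <- 4^(depth_left - 1L)
      kmin <- max(2L, ceiling(n / cap))
      choices <- seq(kmin, min(4L, n))
      k <- choices[sample.int(length(choices), 1L)]
      sizes <- rep(1L, k)
      for (extra in seq_len(n - k)) {
        open <- which(sizes < cap)
        pick <- open[sample.int(length(open), 1L)]
        sizes[pick] <- sizes[pick] + 1L
      }
      for (s in sizes)
        grow(s, depth_left - 1L, acc, height * stats::runif(1, 0.5, 0.9))
      invisible(acc)
    }
    grow(n_leaves, max_depth, NA_character_, 1.0)
    aliases <- rand_alias(length(nodes))
    # aligned aliases are drawn without replacement: an anchor alias maps to
    # at most one node here, so generated labels stay unique
    aligned_pool <- if (!is_anchor && !is.null(aligned_from))
      sample(unique(aligned_from)) else character(0)
    cl_nodes <- lapply(seq_along(nodes), function(i) {
      nd <- nodes[[i]]
      flagged <- !nd$leaf && stats::runif(1) < flag_fraction
      aligned <- ""
      if (length(aligned_pool) && stats::runif(1) < 0.5) {
        aligned <- aligned_pool[1]
        aligned_pool <<- aligned_pool[-1]
      }
      cluster_node(
        accession = nd$accession,
        preferred_alias = aliases[i],
        aligned_alias = aligned,
        additional_aliases = if (stats::runif(1) < 0.3)
          paste0(aliases[i], "-syn") else character(0),
        parent_accession = nd$parent,
        flagged_for_class = flagged,
        confidence = nd$height,
        metadata = list(cell_set_color = sprintf("#%06X",
                                                 sample.int(16^6, 1L) - 1L),
                        cell_set_order = as.character(i)))
    })
    tx <- taxonomy(taxonomy_id, species, brain_region, cl_nodes, is_anchor)
    parents <- taxonomy_parents(tx)
    gt <- list(
      taxonomy_id = taxonomy_id,
      n_nodes = length(cl_nodes),
      n_leaves = as.integer(n_leaves),
      leaves = canonical_sort(taxonomy_leaves(tx)),
      roots = names(parents)[is.na(parents)],
      parents = parents,
      flagged = canonical_sort(taxonomy_accessions(tx)[
        vapply(cl_nodes, `[[`, logical(1), "flagged_for_class")]),
      heights = stats::setNames(vapply(cl_nodes, `[[`, numeric(1), "confidence"),
                                names(parents)),
      metadata_keys = c("cell_set_color", "cell_set_order"))
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      dj <- file.path(dir, paste0(taxonomy_id, "_dendrogram.json"))
      nt <- file.path(dir, paste0(taxonomy_id, "_nomenclature.tsv"))
      write_dendrogram(tx, dj)
      write_nomenclature_table(tx, nt)
      files <- c(dendrogram = dj, nomenclature = nt)
    }
    list(taxonomy = tx, ground_truth = gt, files = files)
  })
}

#' Generate NS-Forest-style marker inputs for a taxonomy
#'
#' One marker row per classed node (leaves plus flagged), with 2–4 genes
#' drawn from a synthetic pool and an F-beta score drawn uniformly on
#' [0.5, 1] — the range in which published NS-Forest marker sets for
#' cortical taxonomies typically land.
#'
#' @param seed integer seed.
#' @param tx taxonomy.
#' @param genes_per_set integer range c(min, max).
#' @param gene_pool pool size (ignored when \code{gene_list} is given).
#' @param fbeta_range uniform draw interval for the score.
#' @param gene_list optional pre-built reference gene list shared across
#'   taxonomies.
#' @param dir optional output directory.
#' @return list: \code{marker_sets}, \code{gene_list},
#'   \code{ground_truth}, \code{files}.
#' @export
generate_markers <- function(seed, tx, genes_per_set = c(2L, 4L),
                             gene_pool = 100L, fbeta_range = c(0.5, 1),
                             gene_list = NULL, dir = NULL) {
  with_seed(seed, {
    if (is.null(gene_list)) {
      ids <- sprintf("GENE:%07d", seq_len(gene_pool))
      gene_list <- data.frame(identifier = ids, symbol = rand_alias(gene_pool),
                              stringsAsFactors = FALSE)
    }
    ids <- gene_list$identifier
    classed <- classed_accessions(tx)
    sets <- lapply(classed, function(a) {
      k <- sample(seq(genes_per_set[1], genes_per_set[2]), 1L)
      marker_set(a, sample(ids, k),
                 stats::runif(1, fbeta_range[1], fbeta_range[2]))
    })
    gt <- list(n_rows = length(sets),
               total_genes = sum(vapply(sets, function(s) length(s$genes),
                                        integer(1))),
               accessions = classed)
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      mf <- file.path(dir, paste0(tx$taxonomy_id, "_markers.tsv"))
      gf <- file.path(dir, "gene_list.tsv")
      write_marker_table(sets, gene_list, mf)
      write_gene_list(gene_list, gf)
      files <- c(markers = mf, gene_list = gf)
    }
    list(marker_sets = sets, gene_list = gene_list, ground_truth = gt,
         files = files)
  })
}

# fixed mini-hierarchy of imported context terms; grouping classes are
# defined so that at least one generated class can satisfy them
fixture_stub <- function(taxonomies) {
  region <- taxonomies[[1]]$brain_region
  rows <- list(
    c("CL:0000000", "cell", "class", "", ""),
    c("STUB:0000001", "neuron", "class", "CL:0000000", ""),
    c("STUB:0000002", "glutamatergic neuron", "class", "STUB:0000001", ""),
    c("STUB:0000003", "GABAergic neuron", "class", "STUB:0000001", ""),
    c("STUB:0000010", "pyramidal morphology", "class", "", ""),
    c("STUB:0000011", "extratelencephalic projection", "class", "", ""),
    c("STUB:0000012", "bipolar morphology", "class", "", ""),
    c(region, "fixture brain region", "class", "", ""),
    c("STUB:0000020", "extratelencephalic glutamatergic neuron", "class",
      "STUB:0000002", ""),
    c("STUB:0000021", "regional pyramidal cell", "class", "STUB:0000001", ""),
    c("STUB:0000022", "bipolar regional neuron", "class", "STUB:0000001", "")
  )
  stub <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[1], label = r[2], kind = r[3], parent = r[4],
               definition_conjuncts = r[5], stringsAsFactors = FALSE)))
  stub$definition_conjuncts[stub$id == "STUB:0000020"] <-
    paste("STUB:0000002",
          paste("CTO:has_soma_location some", region),
          "CTO:bearer_of some STUB:0000011", sep = "|")
  stub$definition_conjuncts[stub$id == "STUB:0000021"] <-
    paste("STUB:0000001",
          paste("CTO:has_soma_location some", region),
          "CTO:bearer_of some STUB:0000010", sep = "|")
  stub$definition_conjuncts[stub$id == "STUB:0000022"] <-
    paste("STUB:0000001",
          paste("CTO:has_soma_location some", region),
          "CTO:bearer_of some STUB:0000012", sep = "|")
  stub$conjuncts <- lapply(stub$definition_conjuncts, function(d)
    lapply(split_multi(d, "|"), parse_conjunct))
  stub
}

#' Generate curation, homology and imports-stub inputs
#'
#' Curation assigns every classed node a parent class from the stub
#' hierarchy; the first classed node of the anchor taxonomy is guaranteed
#' a region + projection + morphology profile satisfying two grouping
#' classes (so structural classification is exercised), and at least one
#' flagged node is excluded from class generation (emulating over-general
#' groupings like "all cells"). Homology groups span 2–3 distinct
#' taxonomies drawn from the classed, non-excluded nodes.
#'
#' @param seed integer seed.
#' @param taxonomies list of taxonomies (>= 1; homology needs >= 2).
#' @param n_groups homology group count to attempt.
#' @param group_sizes candidate sizes (capped at the taxonomy count).
#' @param dir optional output directory.
#' @return list: \code{curation} (named by taxonomy), \code{homology},
#'   \code{stub}, \code{ground_truth}, \code{files}.
#' @export
generate_curation_and_homology <- function(seed, taxonomies, n_groups = 3L,
                                           group_sizes = c(2L, 3L),
                                           dir = NULL) {
  with_seed(seed, {
    stub <- fixture_stub(taxonomies)
    tx_ids <- vapply(taxonomies, `[[`, character(1), "taxonomy_id")
    names(taxonomies) <- tx_ids
    curation <- list()
    excluded <- character(0)
    for (ti in seq_along(taxonomies)) {
      tx <- taxonomies[[ti]]
      classed <- classed_accessions(tx)
      flagged <- canonical_sort(taxonomy_accessions(tx)[
        vapply(tx$nodes, `[[`, logical(1), "flagged_for_class")])
      excl <- if (length(flagged)) flagged[1] else classed[1]
      excluded <- c(excluded, paste(tx$taxonomy_id, excl, sep = "/"))
      recs <- list(curated_class_record(excl, exclude = TRUE))
      for (j in seq_along(classed)) {
        a <- classed[j]
        if (a == excl) next
        force_profile <- ti == 1L && j == which(classed != excl)[1]
        recs[[length(recs) + 1L]] <- curated_class_record(
          a,
          parent_class_ids = sample(c("STUB:0000002", "STUB:0000003"), 1L),
          morphology_term = if (force_profile || stats::runif(1) < 0.3)
            "STUB:0000010" else NA_character_,
          projection_term = if (force_profile || stats::runif(1) < 0.3)
            "STUB:0000011" else NA_character_,
          extra_synonyms = if (stats::runif(1) < 0.2)
            paste0(a, "-extra") else character(0))
        if (force_profile)
          recs[[length(recs)]]$parent_class_ids <- "STUB:0000002"
      }
      curation[[tx$taxonomy_id]] <- recs
    }
    eligible <- lapply(taxonomies, function(tx) {
      cl <- classed_accessions(tx, curation[[tx$taxonomy_id]])
      cl
    })
    homology <- list()
    if (length(taxonomies) >= 2L) {
      for (g in seq_len(n_groups)) {
        k <- min(sample(group_sizes, 1L), length(taxonomies))
        pick_tx <- sample(tx_ids, k)
        members <- do.call(rbind, lapply(pick_tx, function(tid)
          data.frame(taxonomy_id = tid,
                     cluster_accession = sample(eligible[[tid]], 1L),
                     stringsAsFactors = FALSE)))
        homology[[length(homology) + 1L]] <-
          homology_group(sprintf("HG%03d", g), members)
      }
    }
    gt <- list(excluded = excluded,
               group_sizes = vapply(homology, function(g) nrow(g$members),
                                    integer(1)),
               n_curation_rows = vapply(curation, length, integer(1)))
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- character(0)
      for (tid in names(curation)) {
        cf <- file.path(dir, paste0(tid, "_curation.tsv"))
        write_curation_table(curation[[tid]], cf)
        files[paste0("curation_", tid)] <- cf
      }
      if (length(homology)) {
        hf <- file.path(dir, "homology.tsv")
        write_homology_table(homology, hf)
        files["homology"] <- hf
      }
      sf <- file.path(dir, "imports_stub.tsv")
      write_tsv(stub[, c("id", "label", "kind", "parent",
                         "definition_conjuncts")], sf)
      files["imports_stub"] <- sf
    }
    list(curation = curation, homology = homology, stub = stub,
         ground_truth = gt, files = files)
  })
}

#' Generate a complete multi-species input bundle on disk
#'
#' Convenience wrapper producing everything \code{\link{cmd_build}} needs:
#' an anchor (mouse) taxonomy and a marmoset taxonomy aligned to it,
#' markers and gene list, curation, homology, imports stub, a dataset
#' table and a build manifest. Ground truths of all stages are returned.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param n_leaves_anchor,n_leaves_other leaf counts for the two taxonomies.
#' @param max_depth tree depth bound.
#' @param flag_fraction internal-node flagging probability.
#' @export
generate_fixture_set <- function(seed, dir, n_leaves_anchor = 12L,
                                 n_leaves_other = 9L, max_depth = 4L,
                                 flag_fraction = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g1 <- generate_taxonomy(seed, n_leaves_anchor, max_depth, flag_fraction,
                          species = "NCBITaxon:10090",
                          taxonomy_id = "TXMOUSE", is_anchor = TRUE,
                          dir = dir)
  anchor_aliases <- vapply(g1$taxonomy$nodes, `[[`, character(1),
                           "preferred_alias")
  g2 <- generate_taxonomy(seed + 1L, n_leaves_other, max_depth, flag_fraction,
                          species = "NCBITaxon:9483",
                          taxonomy_id = "TXMARMO", is_anchor = FALSE,
                          aligned_from = anchor_aliases, dir = dir)
  m1 <- generate_markers(seed + 2L, g1$taxonomy, dir = dir)
  m2 <- generate_markers(seed + 3L, g2$taxonomy, gene_list = m1$gene_list,
                         dir = dir)
  ch <- generate_curation_and_homology(seed + 4L,
                                       list(g1$taxonomy, g2$taxonomy),
                                       dir = dir)
  datasets <- list(
    dataset_record("DS001", "TXMOUSE",
                   "https://assets.example.org/ds001", "mouse M1 snRNAseq"),
    dataset_record("DS002", "TXMARMO",
                   "https://assets.example.org/ds002", "marmoset M1 snRNAseq"))
  write_dataset_table(datasets, file.path(dir, "datasets.tsv"))
  manifest <- list(
    taxonomies = list(
      list(taxonomy_id = "TXMOUSE", species = "NCBITaxon:10090",
           brain_region = "UBERON:0001384", is_anchor = TRUE,
           dendrogram = basename(g1$files[["dendrogram"]]),
           nomenclature = basename(g1$files[["nomenclature"]]),
           markers = basename(m1$files[["markers"]]),
           curation = "TXMOUSE_curation.tsv"),
      list(taxonomy_id = "TXMARMO", species = "NCBITaxon:9483",
           brain_region = "UBERON:0001384", is_anchor = FALSE,
           dendrogram = basename(g2$files[["dendrogram"]]),
           nomenclature = basename(g2$files[["nomenclature"]]),
           markers = basename(m2$files[["markers"]]),
           curation = "TXMARMO_curation.tsv")),
    gene_list = "gene_list.tsv",
    homology = if ("homology" %in% names(ch$files)) "homology.tsv",
    imports_stub = "imports_stub.tsv",
    datasets = "datasets.tsv")
  write_lines_utf8(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                    pretty = TRUE, null = "null"),
                   file.path(dir, "manifest.json"))
  list(anchor = g1, other = g2, markers = list(TXMOUSE = m1, TXMARMO = m2),
       curation_homology = ch, datasets = datasets,
       manifest = file.path(dir, "manifest.json"))
}
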