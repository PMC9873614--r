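# Independent oracles and tiny fixture builders shared across the suite.
# Oracles use boolean matrix algebra (repeated squaring), a different
# algorithm family than the package's memoized graph walks.

# build a taxonomy from a named parent vector (name -> parent or NA)
tx_from_parents <- function(parents, taxonomy_id = "TX",
                            species = "NCBITaxon:10090",
                            region = "UBERON:0001384",
                            flagged = character(0), is_anchor = TRUE) {
  nodes <- lapply(names(parents), function(a)
    cluster_node(a, preferred_alias = a, parent_accession = parents[[a]],
                 flagged_for_class = a %in% flagged))
  taxonomy(taxonomy_id, species, region, nodes, is_anchor)
}

chain_taxonomy <- function(n = 3L, prefix = "i", ...) {
  acc <- paste0(prefix, seq_len(n))
  parents <- stats::setNames(c(NA_character_, acc[-n]), acc)
  tx_from_parents(parents, flagged = acc, ...)
}

# irreflexive transitive closure by boolean matrix squaring
oracle_closure <- function(edges_from, edges_to) {
  nodes <- sort(unique(c(edges_from, edges_to)))
  n <- length(nodes)
  M <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  M[cbind(edges_from, edges_to)] <- 1L
  repeat {
    M2 <- ((M + M %*% M) > 0) * 1L
    if (identical(M2, M)) break
    M <- M2
  }
  idx <- which(M == 1L, arr.ind = TRUE)
  data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

# brute-force data-driven classification: check every ordered class pair,
# with ancestor sets found by plain iterative parent walking
oracle_data_driven <- function(exemplars, parents) {
  ancestors_of <- function(a) {
    out <- character(0)
    p <- parents[[a]]
    while (!is.na(p)) { out <- c(out, p); p <- parents[[p]] }
    out
  }
  classes <- names(exemplars)
  anc <- lapply(stats::setNames(unique(unlist(exemplars)),
                                unique(unlist(exemplars))), ancestors_of)
  pairs <- list()
  for (a in classes) for (b in classes) {
    if (a == b) next
    if (exemplars[[b]] %in% anc[[exemplars[[a]]]])
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (!length(pairs)) return(data.frame(sub = character(0),
                                        sup = character(0)))
  df <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(df) <- c("sub", "sup")
  df[order(paste(df$sub, df$sup)), , drop = FALSE]
}

# brute-force structural placement: explicit conjunct matching per pair
oracle_structural <- function(named_sup, restr, stub) {
  cls <- stub[stub$kind == "class", , drop = FALSE]
  edges_f <- c(cls$id[nzchar(cls$parent)],
               rep(names(named_sup), lengths(named_sup)))
  edges_t <- c(cls$parent[nzchar(cls$parent)],
               unlist(named_sup, use.names = FALSE))
  anc <- if (length(edges_f)) oracle_closure(edges_f, edges_t)
         else data.frame(from = character(0), to = character(0))
  reach <- function(a, b) a == b ||
    any(anc$from == a & anc$to == b)
  placements <- list()
  grp <- cls[lengths(cls$conjuncts) > 0L, , drop = FALSE]
  for (g in names(named_sup)) {
    for (i in seq_len(nrow(grp))) {
      conj <- grp$conjuncts[[i]]
      named <- Filter(function(x) x$type == "named", conj)[[1]]$id
      ok <- any(vapply(named_sup[[g]], reach, logical(1), b = named))
      if (ok) for (cj in Filter(function(x) x$type == "some", conj)) {
        hit <- FALSE
        for (r in restr[[g]])
          if (r[1] == cj$property && reach(r[2], cj$filler)) hit <- TRUE
        if (!hit) { ok <- FALSE; break }
      }
      if (ok && g != grp$id[i])
        placements[[length(placements) + 1L]] <- c(g, grp$id[i])
    }
  }
  if (!length(placements)) return(data.frame(sub = character(0),
                                             sup = character(0)))
  df <- as.data.frame(do.call(rbind, placements), stringsAsFactors = FALSE)
  names(df) <- c("sub", "sup")
  df[order(paste(df$sub, df$sup)), , drop = FALSE]
}

# random parent vector for a tree of n nodes (node i's parent < i)
random_tree_parents <- function(n, prefix = "n") {
  acc <- sprintf("%s%03d", prefix, seq_len(n))
  parents <- c(NA_character_,
               if (n > 1) acc[vapply(2:n, function(i)
                 sample.int(i - 1L, 1L), integer(1))])
  stats::setNames(parents, acc)
}

pairs_key <- function(df, a = "sub", b = "sup")
  sort(paste(df[[a]], df[[b]]))

fig3_manifest <- system.file("extdata", "fig3", "manifest.json",
                             package = "ccn2ont")
fig4_manifest <- system.file("extdata", "fig4", "manifest.json",
                             package = "ccn2ont")

build_from_manifest <- function(manifest, config = default_config()) {
  inputs <- load_inputs(manifest, config)
  build_ontology(inputs$taxonomies, inputs$marker_sets, inputs$curation,
                 inputs$homology, inputs$gene_list, inputs$datasets,
                 inputs$stub, config)
}
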