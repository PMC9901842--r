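#' Read a GMT pathway-membership file
#'
#' One set per line: `set_id <TAB> description <TAB> member1 <TAB> ...`.
#' Lines with fewer than three fields are malformed and rejected with the
#' offending line number.
#'
#' @param path GMT file path.
#' @return named list of member-id character vectors with a `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated fields")
    ids[i] <- parts[1L]
    desc[i] <- parts[2L]
    sets[[i]] <- unique(parts[-(1:2)])
  }
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write pathway sets as GMT
#'
#' @param sets named list of member-id vectors.
#' @param path output file.
#' @param description optional description per set.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description") %||%
    rep("", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[[i]], sets[[i]]), collapse = "\t"),
    character(1)), path)
}

#' Collapse redundant terms by membership similarity
#'
#' Terms whose member sets have pairwise Jaccard similarity strictly above
#' the threshold are merged greedily by transitive closure (connected
#' components of the similarity graph); each cluster is represented by its
#' largest member set, ties broken by lexicographically smallest id, so
#' the result is deterministic.
#'
#' @param term_sets named list of member-id vectors.
#' @param similarity_threshold Jaccard cut-off (default 0.7, strict).
#' @return list with `sets` (collapsed, representatives only) and
#'   `mapping` (data.frame term -> representative).
#' @export
refine_terms <- function(term_sets, similarity_threshold = 0.7) {
  n <- length(term_sets)
  ids <- names(term_sets)
  if (n == 0L) return(list(sets = term_sets,
                           mapping = data.frame(term = character(),
                                                representative = character())))
  sets <- lapply(term_sets, unique)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    if (uni > 0L && inter / uni > similarity_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  rep_of <- vapply(split(seq_len(n), root), function(members) {
    sizes <- vapply(sets[members], length, 1L)
    best <- members[sizes == max(sizes)]
    best[order(ids[best])][1L]
  }, 1L)
  mapping <- data.frame(term = ids,
                        representative = ids[rep_of[as.character(root)]],
                        row.names = NULL)
  list(sets = term_sets[sort(unique(mapping$representative))],
       mapping = mapping)
}

#' Map significant elements of the three layers onto pathways
#'
#' Proteins and metabolites are looked up in the pathway sets by their own
#' identifier (gene symbol, compound ID); variants are looked up through
#' their mapped gene. Elements found in no pathway are retained with an
#' empty set and reported with a warning, so nothing silently disappears.
#'
#' @param elements data.frame with columns `element_id`, `layer` (one of
#'   proteome/metabolome/gwas) and, for gwas rows, `mapped_gene`.
#' @param pathway_sets named list from [read_gmt()].
#' @return data.frame `element_id`, `layer`, `mapped_gene`, `n_pathways`,
#'   plus a list-column `pathways`.
#' @export
map_elements <- function(elements, pathway_sets) {
  stopifnot(all(c("element_id", "layer") %in% names(elements)))
  bad <- setdiff(unique(elements$layer),
                 c("proteome", "metabolome", "gwas"))
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  path_ids <- names(pathway_sets)
  key <- ifelse(elements$layer == "gwas",
                elements$mapped_gene %||% NA_character_,
                elements$element_id)
  pathways <- lapply(key, function(k) {
    if (is.na(k) || !nzchar(k)) return(character())
    path_ids[vapply(pathway_sets, function(s) k %in% s, logical(1))]
  })
  n_path <- lengths(pathways)
  if (any(n_path == 0L))
    warning(sum(n_path == 0L), " element(s) mapped to no pathway")
  out <- data.frame(element_id = elements$element_id,
                    layer = elements$layer,
                    mapped_gene = if (!is.null(elements$mapped_gene))
                      elements$mapped_gene else NA_character_,
                    n_pathways = n_path,
                    row.names = NULL)
  out$pathways <- pathways
  out
}

#' Build the connective pathway multigraph
#'
#' One node per pathway touched by at least one element. An element
#' attributed to `k >= 2` pathways contributes one labelled edge per
#' unordered pathway pair in its set (`choose(k, 2)` multiedges, coloured
#' by the element's omics layer); an element attributed to exactly one
#' pathway contributes a self-loop on it. Elements with an empty pathway
#' set are skipped (already logged by [map_elements()]).
#'
#' @param mapped output of [map_elements()].
#' @return an `igraph` multigraph with edge attributes `element` and
#'   `layer`.
#' @export
build_graph <- function(mapped) {
  use <- mapped[mapped$n_pathways > 0L, , drop = FALSE]
  if (nrow(use) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  nodes <- sort(unique(unlist(use$pathways)))
  from <- character(); to <- character()
  element <- character(); layer <- character()
  for (i in seq_len(nrow(use))) {
    ps <- sort(use$pathways[[i]])
    if (length(ps) == 1L) {
      pairs <- matrix(c(ps, ps), 1L, 2L)
    } else {
      pairs <- t(utils::combn(ps, 2L))
    }
    from <- c(from, pairs[, 1L]); to <- c(to, pairs[, 2L])
    element <- c(element, rep(use$element_id[i], nrow(pairs)))
    layer <- c(layer, rep(use$layer[i], nrow(pairs)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, element = element, layer = layer),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  g
}

# Newman degree assortativity over the non-loop edges of a multigraph:
# Pearson correlation of the degrees at the two endpoints of each edge.
newman_assortativity <- function(deg_from, deg_to) {
  m <- length(deg_from)
  if (m == 0L) return(NA_real_)
  j <- deg_from; k <- deg_to
  num <- mean(j * k) - mean((j + k) / 2)^2
  den <- mean((j^2 + k^2) / 2) - mean((j + k) / 2)^2
  if (den <= .Machine$double.eps) return(NA_real_)
  num / den
}

#' Summarize a connective graph
#'
#' Centrality of a node is its count of incident non-loop edge endpoints
#' (multiedges counted with multiplicity); each self-loop adds
#' `loop_weight` (0 by default, 2 for the both-endpoints convention). Hub
#' counts are taken strictly above the two thresholds. Degree
#' assortativity is Newman's r: the Pearson correlation of centralities
#' at the endpoints of the non-loop edges; it is undefined (NA, flagged)
#' when all endpoint degrees are equal. Graph size is reported as the
#' edge count (self-loops included), with the node count alongside.
#'
#' @param graph a [build_graph()] result.
#' @param hub_thresholds two centrality thresholds (default `c(10, 20)`).
#' @param loop_weight centrality contribution of a self-loop (0 or 2).
#' @return list with `centrality` (data.frame), `hub_counts`,
#'   `assortativity`, `assortativity_defined`, `size` (edges),
#'   `n_nodes`, `n_self_loops`.
#' @export
summarize_graph <- function(graph, hub_thresholds = c(10L, 20L),
                            loop_weight = 0) {
  ends <- igraph::as_edgelist(graph, names = TRUE)
  is_loop <- ends[, 1L] == ends[, 2L]
  nodes <- igraph::V(graph)$name %||% character(0)
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  if (any(!is_loop)) {
    tab <- table(c(ends[!is_loop, 1L], ends[!is_loop, 2L]))
    deg[names(tab)] <- as.numeric(tab)
  }
  loops <- stats::setNames(numeric(length(nodes)), nodes)
  if (any(is_loop)) {
    tab <- table(ends[is_loop, 1L])
    loops[names(tab)] <- as.numeric(tab)
  }
  centrality <- deg + loop_weight * loops
  r <- newman_assortativity(centrality[ends[!is_loop, 1L]],
                            centrality[ends[!is_loop, 2L]])
  list(
    centrality = data.frame(pathway = nodes, centrality = centrality,
                            self_loops = loops, row.names = NULL),
    hub_counts = stats::setNames(
      vapply(hub_thresholds, function(t) sum(centrality > t), 1L),
      paste0("gt_", hub_thresholds)),
    assortativity = r,
    assortativity_defined = !is.na(r),
    size = nrow(ends),
    n_nodes = length(nodes),
    n_self_loops = sum(is_loop))
}

#' Layer-intersection report over pathways
#'
#' For every pathway touched by at least one mapped element, reports which
#' omics layers reach it and the element lists per layer; the headline
#' number is the count of pathways reached by all three layers.
#'
#' @param mapped output of [map_elements()].
#' @return list with `report` (data.frame: pathway, per-layer presence and
#'   element strings, `n_layers`) and `triple_layer_count`.
#' @export
intersection_report <- function(mapped) {
  use <- mapped[mapped$n_pathways > 0L, , drop = FALSE]
  if (nrow(use) == 0L)
    return(list(report = data.frame(pathway = character(),
                                    proteome = character(),
                                    metabolome = character(),
                                    gwas = character(),
                                    n_layers = integer()),
                triple_layer_count = 0L))
  long <- data.frame(
    pathway = unlist(use$pathways),
    layer = rep(use$layer, use$n_pathways),
    element = rep(use$element_id, use$n_pathways))
  layers <- c("proteome", "metabolome", "gwas")
  paths <- sort(unique(long$pathway))
  rows <- lapply(paths, function(p) {
    sub <- long[long$pathway == p, , drop = FALSE]
    members <- lapply(layers, function(l)
      sort(unique(sub$element[sub$layer == l])))
    names(members) <- layers
    data.frame(pathway = p,
               proteome = paste(members$proteome, collapse = ";"),
               metabolome = paste(members$metabolome, collapse = ";"),
               gwas = paste(members$gwas, collapse = ";"),
               n_layers = sum(lengths(members) > 0L))
  })
  report <- do.call(rbind, rows)
  list(report = report,
       triple_layer_count = sum(report$n_layers == 3L))
}
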