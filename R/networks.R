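# Metabolite-protein bipartite network and protein-protein interaction
# network analyses. Graphs are undirected and simple; hubs are defined by
# a degree threshold (default 10, the neighbor count of the CAD hub).

#' Build the metabolite-protein bipartite network
#'
#' Nodes are the distinct metabolites and proteins of the link table,
#' edges the distinct link pairs. Node attributes: `type`
#' (`"metabolite"` or `"protein"`), `changed` (metabolites with a
#' reported change), and `multi_changed` (proteins linked to at least
#' two changed metabolites, the class highlighted in the study's network
#' figure).
#'
#' @param links link table from [read_links()].
#' @param changes metabolite change table (or character vector of changed
#'   metabolite ids), or `NULL`.
#' @param min_changed_links threshold for the `multi_changed` protein
#'   class (default 2).
#' @return an undirected simple igraph object.
#' @export
build_bipartite <- function(links, changes = NULL, min_changed_links = 2L) {
  pair <- unique(links[, c("metabolite_id", "uniprot_id")])
  if (nrow(pair) > 0L && any(pair$metabolite_id == pair$uniprot_id)) {
    stop("self-loop: identical metabolite and protein identifier",
         call. = FALSE)
  }
  metabolites <- sort(unique(pair$metabolite_id), method = "radix")
  proteins <- sort(unique(pair$uniprot_id), method = "radix")
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(metabolites) + length(proteins),
                            name = c(metabolites, proteins),
                            type = rep(c("metabolite", "protein"),
                                       c(length(metabolites),
                                         length(proteins))))
  if (nrow(pair) > 0L) {
    g <- igraph::add_edges(g, rbind(pair$metabolite_id, pair$uniprot_id))
  }
  g <- igraph::simplify(g)
  changed <- if (is.data.frame(changes)) changes$metabolite_id else changes
  changed <- unique(changed)
  igraph::V(g)$changed <- igraph::V(g)$name %in% changed
  multi <- collect_metabolite_proteins(pair, changed,
                                       min_links = min_changed_links)
  igraph::V(g)$multi_changed <- igraph::V(g)$name %in% multi$uniprot_id
  g
}

#' Build a protein-protein interaction network from an edge list
#'
#' Consumes a String-style export: two protein columns and an optional
#' combined confidence score. Scores on the 0-1000 String scale are
#' rescaled to \\[0, 1\\] edge weights.
#'
#' @param edges data frame whose first two columns are protein
#'   identifiers; an optional `combined_score` column becomes the edge
#'   weight.
#' @param min_score drop edges below this confidence (on the rescaled
#'   0-1 scale); `NULL` keeps all.
#' @return an undirected simple igraph object.
#' @export
build_ppi <- function(edges, min_score = NULL) {
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- a != b
  w <- NULL
  if ("combined_score" %in% names(edges)) {
    w <- as.numeric(edges$combined_score)
    if (length(w) > 0L && any(w > 1, na.rm = TRUE)) w <- w / 1000
    if (any(w < 0 | w > 1, na.rm = TRUE)) {
      stop("confidence weights must lie in [0, 1] after rescaling",
           call. = FALSE)
    }
  }
  if (!is.null(min_score) && !is.null(w)) keep <- keep & w >= min_score
  a <- a[keep]; b <- b[keep]
  nodes <- sort(unique(c(a, b)), method = "radix")
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(a) > 0L) {
    g <- igraph::add_edges(g, rbind(a, b))
    if (!is.null(w)) igraph::E(g)$weight <- w[keep]
  }
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Read a String-style protein-protein edge list
#'
#' @param path TSV/CSV file whose first two columns are protein nodes;
#'   an optional `combined_score` column carries confidence.
#' @param sep delimiter, auto-detected when `NULL`.
#' @return data frame of edges.
#' @export
read_string_edges <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("edge list not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (ncol(df) < 2L) stop("edge list needs two node columns",
                          call. = FALSE)
  df
}

#' Find hub nodes by degree
#'
#' @param graph an igraph object.
#' @param min_degree hub threshold (default 10).
#' @return data frame with columns `node`, `degree`, sorted by degree
#'   descending then name ascending.
#' @export
find_hubs <- function(graph, min_degree = 10L) {
  stopifnot(min_degree >= 1L)
  deg <- igraph::degree(graph)
  hubs <- deg[deg >= min_degree]
  ord <- order(-hubs, names(hubs), method = "radix")
  data.frame(node = names(hubs)[ord], degree = unname(hubs[ord]),
             stringsAsFactors = FALSE)
}

#' Induced subgraph around a hub
#'
#' The hub plus all of its direct neighbors, with every edge among them.
#'
#' @param graph an igraph object.
#' @param hub node name.
#' @return igraph object of the neighborhood.
#' @export
hub_neighborhood <- function(graph, hub) {
  if (!hub %in% igraph::V(graph)$name) {
    stop("unknown hub node: ", hub, call. = FALSE)
  }
  nbrs <- igraph::neighbors(graph, hub)
  igraph::induced_subgraph(graph, c(hub, igraph::V(graph)$name[nbrs]))
}

#' Connected clusters above a size threshold
#'
#' @param graph an igraph object.
#' @param min_size minimum component size (default 1).
#' @return list of character vectors of node names, largest component
#'   first (ties by first node name).
#' @export
connected_clusters <- function(graph, min_size = 1L) {
  stopifnot(min_size >= 1L)
  comp <- igraph::components(graph)
  sets <- split(igraph::V(graph)$name, comp$membership)
  sets <- lapply(sets, sort, method = "radix")
  sets <- sets[vapply(sets, length, 1L) >= min_size]
  first <- vapply(sets, function(s) s[[1]], character(1))
  ord <- order(-vapply(sets, length, 1L), first, method = "radix")
  unname(sets[ord])
}
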