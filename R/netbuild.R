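#' Build the DE-restricted interaction network
#'
#' Restricts a weighted edge list to edges whose two endpoints are both DE
#' genes and whose confidence reaches \code{min_confidence}. Self-loops are
#' dropped; duplicate unordered pairs are collapsed keeping the maximum
#' confidence; genes with no surviving edge do not become nodes.
#'
#' @param edge_list data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{confidence} (numeric, >= 0).
#' @param de_genes character vector of DE gene ids.
#' @param min_confidence minimum edge confidence kept; default 0.
#' @return An undirected \code{igraph} graph with edge attribute
#'   \code{weight} (confidence).
#' @export
build_network <- function(edge_list, de_genes, min_confidence = 0) {
  stopifnot(is.data.frame(edge_list), min_confidence >= 0)
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% names(edge_list)))
    stop("edge_list needs columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(edge_list$gene_a) | is.na(edge_list$gene_b) |
                 !is.finite(edge_list$confidence) | edge_list$confidence < 0)
  if (length(bad))
    stop("malformed edge rows at lines: ", paste(head(bad, 10L), collapse = ", "))
  a <- as.character(edge_list$gene_a)
  b <- as.character(edge_list$gene_b)
  w <- as.numeric(edge_list$confidence)
  keep <- a != b & a %in% de_genes & b %in% de_genes & w >= min_confidence
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  # collapse duplicate unordered pairs, keeping max confidence
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key)) {
    wmax <- tapply(w, key, max)
    first <- !duplicated(key)
    lo <- lo[first]; hi <- hi[first]
    w <- as.numeric(wmax[key[first]])
  }
  if (!length(lo)) {
    warning("no edges survive filtering; empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, weight = w, stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Remove small components and/or keep the largest
#'
#' Drops connected components with fewer than \code{min_component_size}
#' nodes; with \code{keep_largest_only} retains only the largest component by
#' node count (ties broken by the component containing the lexicographically
#' smallest node id).
#'
#' @param network an undirected igraph graph.
#' @param min_component_size minimum component node count kept; default 5.
#' @param keep_largest_only keep only the largest component; default TRUE.
#' @return The filtered igraph graph.
#' @export
filter_components <- function(network, min_component_size = 5,
                              keep_largest_only = TRUE) {
  stopifnot(min_component_size >= 1)
  if (igraph::vcount(network) == 0L) {
    warning("empty network")
    return(network)
  }
  comp <- igraph::components(network)
  keep_comp <- which(comp$csize >= min_component_size)
  if (keep_largest_only && length(keep_comp)) {
    sizes <- comp$csize[keep_comp]
    cand <- keep_comp[sizes == max(sizes)]
    if (length(cand) > 1L) {
      smallest <- vapply(cand, function(ci) {
        min(igraph::V(network)$name[comp$membership == ci])
      }, character(1))
      cand <- cand[order(smallest)][1]
    }
    keep_comp <- cand
  }
  keep_v <- which(comp$membership %in% keep_comp)
  out <- igraph::induced_subgraph(network, keep_v)
  if (igraph::vcount(out) == 0L) warning("all components removed; empty network")
  out
}
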