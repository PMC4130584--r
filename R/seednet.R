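#' Extract the direct neighborhood of seed genes
#'
#' Members are the non-seed nodes adjacent to at least one seed (one hop
#' only); each carries \code{seed_degree}, the number of distinct seeds it
#' touches. Members adjacent to every seed form the \code{core} tier, the
#' rest are \code{peripheral}. The induced subgraph over seeds plus members
#' is returned.
#'
#' @param network an undirected igraph graph.
#' @param seeds character vector of seed gene ids; seeds absent from the
#'   network are dropped with a warning.
#' @return A \code{seed_subnetwork}: list with \code{seeds},
#'   \code{members} (data.frame gene, seed_degree, tier, sorted by
#'   decreasing seed_degree then gene id) and \code{graph}.
#' @export
extract_seed_network <- function(network, seeds) {
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, igraph::V(network)$name)
  if (!length(present)) stop("none of the seeds are present in the network")
  if (length(present) < length(seeds))
    warning("seeds absent from network dropped: ",
            paste(setdiff(seeds, present), collapse = ", "))
  adj <- lapply(present, function(s)
    setdiff(igraph::V(network)$name[as.integer(
      igraph::neighbors(network, s))], present))
  members <- sort(unique(unlist(adj)))
  sd_ <- vapply(members, function(m)
    sum(vapply(adj, function(a) m %in% a, logical(1))), integer(1))
  tier <- ifelse(sd_ == length(present), "core", "peripheral")
  df <- data.frame(gene = members, seed_degree = unname(sd_),
                   tier = unname(tier), stringsAsFactors = FALSE)
  df <- df[order(-df$seed_degree, df$gene), ]
  rownames(df) <- NULL
  sub <- igraph::induced_subgraph(network, c(present, members))
  structure(list(seeds = present, members = df, graph = sub),
            class = "seed_subnetwork")
}

#' @export
print.seed_subnetwork <- function(x, ...) {
  cat(sprintf("seed_subnetwork: %d seeds, %d members (%d core)\n",
              length(x$seeds), nrow(x$members),
              sum(x$members$tier == "core")))
  invisible(x)
}

#' Pick seeds as the DE genes annotated to a term
#'
#' Resolves \code{term_id} in the catalog and returns its member genes
#' present in \code{genes} — how one turns, e.g., an autophagy annotation
#' into seed genes for [extract_seed_network()].
#'
#' @param catalog a \code{gene_set_catalog}.
#' @param term_id a term id in the catalog.
#' @param genes gene universe to intersect with (e.g. one layer's DE genes).
#' @return character vector of seed gene ids.
#' @export
seeds_from_term <- function(catalog, term_id, genes) {
  i <- match(term_id, catalog$term_id)
  if (is.na(i)) stop("term not in catalog: ", term_id)
  intersect(catalog$genes[[i]], genes)
}
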