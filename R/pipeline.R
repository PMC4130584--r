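#' Pipeline control parameters
#'
#' Collects every tunable threshold of the analysis in one validated list.
#' Defaults follow the conventions of the method: raw t-test filter at 0.05,
#' component-size floor 5 with only the largest component kept, kappa edge
#' rule strictly greater than 0.3, group merge at 50% of the smaller group,
#' direction call at 60% of hit genes, Bonferroni-adjusted term cut 0.05.
#'
#' @param alpha_de DE significance level on the raw t-test p.
#' @param alpha_terms significance level on the Bonferroni-adjusted term p.
#' @param min_confidence minimum edge confidence kept.
#' @param min_component_size minimum connected-component size kept.
#' @param keep_largest_only keep only the largest component.
#' @param layer_priority permutation of the three canonical layers used for
#'   multi-localization and propagation tie-breaks.
#' @param kappa_threshold kappa edge threshold (strict).
#' @param share_threshold group merge threshold on the shared fraction of
#'   the smaller group.
#' @param pct_up_threshold direction-call threshold on the up fraction.
#' @param min_hits minimum term hits to be tested.
#' @param background \code{"expression"} (all genes on the matrix) or a
#'   character vector of gene ids.
#' @param ease use the EASE-style hypergeometric tail.
#' @param cluster_floor correlation floor of the direction clusterer.
#' @return A \code{layint_control} list.
#' @export
layint_control <- function(alpha_de = 0.05, alpha_terms = 0.05,
                           min_confidence = 0, min_component_size = 5,
                           keep_largest_only = TRUE,
                           layer_priority = CANONICAL_LAYERS,
                           kappa_threshold = 0.3, share_threshold = 0.5,
                           pct_up_threshold = 0.6, min_hits = 2,
                           background = "expression", ease = FALSE,
                           cluster_floor = 0) {
  stopifnot(alpha_de > 0, alpha_de < 1, alpha_terms > 0, alpha_terms < 1,
            min_confidence >= 0, min_component_size >= 1,
            is.logical(keep_largest_only),
            setequal(layer_priority, CANONICAL_LAYERS),
            kappa_threshold >= -1, kappa_threshold <= 1,
            share_threshold > 0, share_threshold <= 1,
            pct_up_threshold > 0.5, pct_up_threshold <= 1, min_hits >= 1)
  structure(list(alpha_de = alpha_de, alpha_terms = alpha_terms,
                 min_confidence = min_confidence,
                 min_component_size = min_component_size,
                 keep_largest_only = keep_largest_only,
                 layer_priority = layer_priority,
                 kappa_threshold = kappa_threshold,
                 share_threshold = share_threshold,
                 pct_up_threshold = pct_up_threshold, min_hits = min_hits,
                 background = background, ease = ease,
                 cluster_floor = cluster_floor),
            class = "layint_control")
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Layered interactome analysis
#'
#' Drives the full analysis: differential expression with direction
#' clustering, DE-restricted network assembly and topology filtering,
#' subcellular layer assignment with propagation, per-layer
#' over-representation with Bonferroni control, kappa grouping of the
#' significant terms with direction labels, and optionally a seed-gene
#' subnetwork.
#'
#' @param dataset an [expression_dataset()].
#' @param edges data.frame edge list (gene_a, gene_b, confidence).
#' @param locmap named list gene -> localization labels.
#' @param catalog a [gene_set_catalog()].
#' @param control a [layint_control()].
#' @param seeds optional seed genes for [extract_seed_network()]: a
#'   character vector of gene ids, or \code{"term:<id>"} to use the DE genes
#'   annotated to a catalog term.
#' @return An object of class \code{"layint"}: list with \code{de},
#'   \code{network}, \code{layered}, \code{distribution}, \code{enrichment}
#'   (per-layer list), \code{kappa_graphs}, \code{groups}, \code{seednet},
#'   \code{directions}, \code{counts}, \code{control}.
#' @export
layint <- function(dataset, edges, locmap, catalog,
                   control = layint_control(), seeds = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(catalog, "gene_set_catalog"),
            inherits(control, "layint_control"))
  de <- with_stage("expression", {
    r <- select_de_genes(dataset, control$alpha_de)
    cluster_directions(dataset, r, control$cluster_floor)
  })
  directions <- setNames(de$direction, de$gene)
  de_genes <- de$gene[de$direction != "not_de"]
  counts <- list(de_total = length(de_genes),
                 de_up = sum(de$direction == "up"),
                 de_down = sum(de$direction == "down"),
                 de_unclustered = sum(de$direction == "unclustered"))

  g0 <- with_stage("netbuild", suppressWarnings(
    build_network(edges, de_genes, control$min_confidence)))
  counts$network_nodes_prefilter <- igraph::vcount(g0)
  counts$network_edges_prefilter <- igraph::ecount(g0)
  g <- with_stage("netbuild", suppressWarnings(
    filter_components(g0, control$min_component_size,
                      control$keep_largest_only)))
  counts$network_nodes <- igraph::vcount(g)
  counts$network_edges <- igraph::ecount(g)

  if (igraph::vcount(g) == 0L) {
    warning("filtered network is empty; downstream stages are skipped")
    out <- list(de = de, network = g, layered = NULL,
                distribution = layer_distribution_empty(),
                enrichment = setNames(vector("list", 3), CANONICAL_LAYERS),
                kappa_graphs = list(), groups = list(), seednet = NULL,
                directions = directions, counts = counts, control = control)
    class(out) <- "layint"
    return(out)
  }

  layered <- with_stage("layering",
    assign_layers(g, locmap, control$layer_priority))
  distribution <- layer_distribution(layered, directions)

  background <- if (identical(control$background, "expression"))
    dataset$gene_ids else control$background

  enrichment <- list(); kappa_graphs <- list(); groups <- list()
  for (l in CANONICAL_LAYERS) {
    enr <- with_stage("enrichment", suppressWarnings(
      enrich_layer(layered, l, catalog, background, directions,
                   alpha = control$alpha_terms, min_hits = control$min_hits,
                   ease = control$ease)))
    enrichment[[l]] <- enr
    if (nrow(enr)) {
      reference <- names(layered$layer)[layered$layer == l]
      kg <- with_stage("grouping",
        build_kappa_graph(enr, reference, control$kappa_threshold))
      kappa_graphs[[l]] <- kg
      membs <- with_stage("grouping", merge_groups(kg, control$share_threshold))
      for (mb in membs)
        groups[[length(groups) + 1L]] <- with_stage("grouping",
          label_and_direct(mb, enr, directions, control$pct_up_threshold))
    }
  }

  sn <- NULL
  if (!is.null(seeds)) {
    if (length(seeds) == 1L && startsWith(seeds, "term:"))
      seeds <- seeds_from_term(catalog, sub("^term:", "", seeds),
                               igraph::V(g)$name)
    sn <- with_stage("seednet", extract_seed_network(g, seeds))
  }

  out <- list(de = de, network = g, layered = layered,
              distribution = distribution, enrichment = enrichment,
              kappa_graphs = kappa_graphs, groups = groups, seednet = sn,
              directions = directions, counts = counts, control = control)
  class(out) <- "layint"
  out
}

layer_distribution_empty <- function() {
  data.frame(layer = c(CANONICAL_LAYERS, "total"), up = 0L, down = 0L,
             total_pct = 0, stringsAsFactors = FALSE)
}

#' @export
print.layint <- function(x, ...) {
  cat("Layered interactome analysis\n")
  cat(sprintf("  DE genes: %d (%d up, %d down, %d unclustered)\n",
              x$counts$de_total, x$counts$de_up, x$counts$de_down,
              x$counts$de_unclustered))
  cat(sprintf("  Network: %d nodes, %d edges (from %d/%d before filtering)\n",
              x$counts$network_nodes, x$counts$network_edges,
              x$counts$network_nodes_prefilter,
              x$counts$network_edges_prefilter))
  cat("  Layer distribution:\n")
  print(render_table1(x))
  nsig <- vapply(x$enrichment, function(e) if (is.null(e)) 0L else nrow(e),
                 integer(1))
  cat(sprintf("  Significant terms: %s\n",
              paste(sprintf("%s %d", names(nsig), nsig), collapse = ", ")))
  cat(sprintf("  Annotation groups: %d\n", length(x$groups)))
  invisible(x)
}

#' @export
summary.layint <- function(object, ...) {
  gs <- groups_table(object)
  out <- list(counts = object$counts, table1 = render_table1(object),
              groups = gs,
              m_per_layer = vapply(object$enrichment, function(e)
                if (is.null(e)) 0L else attr(e, "m") %||% 0L, integer(1)))
  class(out) <- "summary.layint"
  out
}

#' @export
print.summary.layint <- function(x, ...) {
  print(x$table1)
  cat("\nAnnotation groups:\n")
  print(x$groups)
  invisible(x)
}

#' Tabulate annotation groups
#'
#' @param x a \code{layint} object.
#' @return data.frame with one row per group: group_id, layer, direction,
#'   label terms, member count, leading Bonferroni p.
#' @export
groups_table <- function(x) {
  if (!length(x$groups))
    return(data.frame(group_id = integer(), layer = character(),
                      direction = character(), label_terms = character(),
                      n_terms = integer(), n_genes = integer(),
                      leading_p_bonferroni = numeric(),
                      members = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(x$groups), function(i) {
    g <- x$groups[[i]]
    data.frame(group_id = i, layer = g$layer, direction = g$direction,
               label_terms = paste(g$label_terms, collapse = ";"),
               n_terms = length(g$members), n_genes = g$n_genes,
               leading_p_bonferroni = g$leading_p_bonferroni,
               members = paste(g$members, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Render the layer distribution table
#'
#' Produces the three-layer distribution table: up/down counts per layer
#' and the layer's percentage of all directed nodes (half-up, one decimal);
#' the Total row carries the up/down column sums and the grand total count.
#'
#' @param x a \code{layint} object, a [layer_distribution()] data.frame, or
#'   a data.frame of injected counts with columns \code{layer}, \code{up},
#'   \code{down} (one row per canonical layer).
#' @return data.frame with rows Plasma membrane / Cytoplasm / Nucleus /
#'   Total and columns Localization, Up.regulated, Down.regulated,
#'   Total.pct.
#' @export
render_table1 <- function(x) {
  if (inherits(x, "layint")) x <- x$distribution
  stopifnot(is.data.frame(x), all(c("layer", "up", "down") %in% names(x)))
  x <- x[x$layer %in% CANONICAL_LAYERS, , drop = FALSE]
  x <- x[match(CANONICAL_LAYERS, x$layer), , drop = FALSE]
  if (anyNA(x$layer)) stop("counts must cover the three canonical layers")
  ud <- x$up + x$down
  total <- sum(ud)
  pct <- if (total > 0) round_half_up(100 * ud / total, 1) else rep(0, 3)
  data.frame(
    Localization = c("Plasma membrane", "Cytoplasm", "Nucleus", "Total"),
    Up.regulated = c(x$up, sum(x$up)),
    Down.regulated = c(x$down, sum(x$down)),
    Total.pct = c(pct, total),
    stringsAsFactors = FALSE)
}

#' Plot a layered interactome analysis
#'
#' Draws the filtered network in three horizontal tiers (plasma membrane on
#' top, nucleus at the bottom), nodes coloured by direction (up = red,
#' down = green, otherwise grey), x-positions in deterministic sorted-id
#' order within each tier.
#'
#' @param x a \code{layint} object.
#' @param ... passed to \code{plot.igraph}.
#' @export
plot.layint <- function(x, ...) {
  if (is.null(x$layered)) {
    warning("nothing to plot: empty network")
    return(invisible(x))
  }
  g <- x$layered$network
  nm <- igraph::V(g)$name
  ypos <- c(plasma_membrane = 2, cytoplasm = 1, nucleus = 0)
  y <- unname(ypos[x$layered$layer[nm]])
  xx <- numeric(length(nm))
  for (l in CANONICAL_LAYERS) {
    i <- which(x$layered$layer[nm] == l)
    xx[i][order(nm[i])] <- seq_along(i)
  }
  col <- c(up = "firebrick", down = "forestgreen")[x$directions[nm]]
  col[is.na(col)] <- "grey70"
  igraph::plot.igraph(g, layout = cbind(xx, y), vertex.color = unname(col),
                      vertex.size = 4, vertex.label = NA, ...)
  invisible(x)
}
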