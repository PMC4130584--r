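#' Default localization label mapping
#'
#' Maps free-text subcellular localization labels (HPRD-style) to the three
#' canonical layers or \code{"other"}. Matching is case-insensitive on the
#' trimmed label.
#'
#' @return data.frame with columns \code{label}, \code{canonical}.
#' @export
default_label_map <- function() {
  data.frame(
    label = c("plasma membrane", "plasma_membrane", "cell membrane", "membrane",
              "cell surface", "cytoplasm", "cytosol", "cytoplasmic",
              "nucleus", "nuclear", "nucleolus", "nucleoplasm",
              "mitochondrion", "mitochondria", "endoplasmic reticulum", "golgi",
              "golgi apparatus", "lysosome", "peroxisome", "extracellular",
              "secreted", "other"),
    canonical = c("plasma_membrane", "plasma_membrane", "plasma_membrane",
                  "plasma_membrane", "plasma_membrane", "cytoplasm", "cytoplasm",
                  "cytoplasm", "nucleus", "nucleus", "nucleus", "nucleus",
                  "other", "other", "other", "other", "other", "other", "other",
                  "other", "other", "other"),
    stringsAsFactors = FALSE)
}

#' Resolve a gene's localization labels to one canonical layer
#'
#' Maps each raw label through the label map, then returns the
#' highest-priority canonical layer present. Genes whose labels map only to
#' \code{"other"} (or that have no labels) get \code{NA}: the three-layer
#' model has no fourth stratum, so such genes are treated as unannotated and
#' later propagated.
#'
#' @param localizations character vector of raw localization labels.
#' @param priority permutation of the three canonical layers; default
#'   plasma_membrane, cytoplasm, nucleus.
#' @param label_map mapping data.frame as from [default_label_map()].
#' @return One of the canonical layers, or \code{NA_character_}.
#' @export
canonical_layer <- function(localizations,
                            priority = CANONICAL_LAYERS,
                            label_map = default_label_map()) {
  stopifnot(setequal(priority, CANONICAL_LAYERS), length(priority) == 3L)
  if (!length(localizations)) return(NA_character_)
  key <- tolower(trimws(localizations))
  hit <- match(key, label_map$label)
  if (anyNA(hit))
    stop("unknown localization label(s): ",
         paste(unique(localizations[is.na(hit)]), collapse = ", "))
  canon <- label_map$canonical[hit]
  for (layer in priority) if (layer %in% canon) return(layer)
  NA_character_
}

#' Assign every network node to a subcellular layer
#'
#' Annotated nodes get [canonical_layer()] of their localization record.
#' Each unannotated node is placed in the majority layer among annotated
#' nodes at minimal breadth-first (hop) distance; majority ties are broken by
#' the priority order. Propagation reads annotated nodes only, so the result
#' does not depend on node input order.
#'
#' @param network an undirected igraph graph (typically the filtered DE
#'   network, a single connected component).
#' @param locmap named list: gene id -> character vector of raw localization
#'   labels.
#' @param priority permutation of the three canonical layers.
#' @param label_map mapping data.frame as from [default_label_map()].
#' @return A \code{layered_interactome}: list with \code{network},
#'   \code{layer} (named character) and \code{provenance} (named character,
#'   \code{"annotated"} or \code{"propagated"}).
#' @export
assign_layers <- function(network, locmap, priority = CANONICAL_LAYERS,
                          label_map = default_label_map()) {
  nodes <- igraph::V(network)$name
  layer <- setNames(rep(NA_character_, length(nodes)), nodes)
  for (g in intersect(nodes, names(locmap)))
    layer[g] <- canonical_layer(locmap[[g]], priority, label_map)
  annotated <- names(layer)[!is.na(layer)]
  unann <- names(layer)[is.na(layer)]
  provenance <- setNames(ifelse(is.na(layer), "propagated", "annotated"), nodes)
  if (length(unann)) {
    if (!length(annotated))
      stop("no annotated node reachable; orphan nodes: ",
           paste(head(unann, 10L), collapse = ", "))
    d <- igraph::distances(network, v = unann, to = annotated, weights = NA)
    for (i in seq_along(unann)) {
      di <- d[i, ]
      if (all(!is.finite(di)))
        stop("no annotated node reachable from: ", unann[i])
      nearest <- annotated[di == min(di[is.finite(di)])]
      votes <- table(factor(layer[nearest], levels = priority))
      layer[unann[i]] <- priority[which.max(votes)]   # which.max: first max = priority tie-break
    }
  }
  structure(list(network = network, layer = layer, provenance = provenance),
            class = "layered_interactome")
}

#' @export
print.layered_interactome <- function(x, ...) {
  cat(sprintf("layered_interactome: %d nodes, %d edges\n",
              igraph::vcount(x$network), igraph::ecount(x$network)))
  print(table(x$layer)[CANONICAL_LAYERS])
  cat(sprintf("(%d annotated, %d propagated)\n",
              sum(x$provenance == "annotated"), sum(x$provenance == "propagated")))
  invisible(x)
}

#' Per-layer distribution of up/down nodes
#'
#' Counts up- and down-regulated nodes per layer; layer percentage is
#' 100 * (up + down) / grand total of directed nodes, rounded half-up to one
#' decimal. Nodes with any other direction label are not counted.
#'
#' @param layered a \code{layered_interactome}.
#' @param directions named character vector, node -> direction
#'   (\code{up}/\code{down}/other).
#' @return data.frame with one row per layer plus a Total row; columns
#'   layer, up, down, total_pct (grand total count in the Total row,
#'   percentage in layer rows).
#' @export
layer_distribution <- function(layered, directions) {
  stopifnot(inherits(layered, "layered_interactome"))
  nodes <- names(layered$layer)
  if (!all(nodes %in% names(directions)))
    stop("directions must cover every network node")
  dir <- directions[nodes]
  counts <- lapply(CANONICAL_LAYERS, function(l) {
    in_l <- layered$layer == l
    c(up = sum(in_l & dir == "up"), down = sum(in_l & dir == "down"))
  })
  counts <- do.call(rbind, counts)
  ud <- counts[, "up"] + counts[, "down"]
  total <- sum(ud)
  pct <- if (total > 0) round_half_up(100 * ud / total, 1) else rep(0, 3)
  out <- data.frame(layer = c(CANONICAL_LAYERS, "total"),
                    up = c(counts[, "up"], sum(counts[, "up"])),
                    down = c(counts[, "down"], sum(counts[, "down"])),
                    total_pct = c(pct, total),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
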