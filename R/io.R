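#' Gene-set catalog constructor
#'
#' @param term_id unique term identifiers.
#' @param term_name term display names.
#' @param source per-term source tag, one of \code{GO_BP}, \code{KEGG},
#'   \code{other}.
#' @param genes list of non-empty character vectors of member genes.
#' @return A \code{gene_set_catalog}.
#' @export
gene_set_catalog <- function(term_id, term_name = term_id,
                             source = rep("other", length(term_id)), genes) {
  term_id <- as.character(term_id)
  if (anyDuplicated(term_id)) stop("duplicate term ids")
  if (length(genes) != length(term_id)) stop("genes list length mismatch")
  if (any(!lengths(genes))) stop("gene sets must be non-empty")
  if (!all(source %in% c("GO_BP", "KEGG", "other")))
    stop("source must be GO_BP, KEGG or other")
  structure(list(term_id = term_id, term_name = as.character(term_name),
                 source = as.character(source),
                 genes = lapply(genes, as.character)),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("gene_set_catalog: %d terms, sizes %d..%d\n",
              length(x$term_id), min(lengths(x$genes)), max(lengths(x$genes))))
  invisible(x)
}

#' Write / read expression TSV
#'
#' Genes in rows, samples in columns. Line 1 is the header (\code{gene} plus
#' sample ids); line 2 is the condition line (\code{#condition} plus one
#' group label per sample); data rows follow.
#'
#' @param dataset an [expression_dataset()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(dataset, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(paste(x, collapse = "\t"), con, sep = "\n")
  wl(c("gene", dataset$sample_ids))
  wl(c("#condition", as.character(dataset$condition)))
  for (i in seq_along(dataset$gene_ids))
    wl(c(dataset$gene_ids[i],
         formatC(dataset$values[i, ], format = "g", digits = 15)))
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file too short: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cond <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (cond[1] != "#condition") stop("missing #condition line in ", path)
  sample_ids <- hdr[-1]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  gene_ids <- vapply(body, `[`, character(1), 1)
  values <- t(vapply(body, function(r) as.numeric(r[-1]),
                     numeric(length(sample_ids))))
  expression_dataset(values, gene_ids, sample_ids,
                     factor(cond[-1], levels = unique(cond[-1])))
}

#' Write / read a 3-column edge list TSV (gene_a, gene_b, confidence)
#'
#' @param edges data.frame with columns gene_a, gene_b, confidence.
#' @param path file path.
#' @return \code{path} (write) or the edge data.frame (read).
#' @export
write_edge_tsv <- function(edges, path) {
  df <- data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                   confidence = formatC(edges$confidence, format = "g", digits = 15))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  bad <- which(is.na(df$gene_a) | is.na(df$gene_b) | is.na(df$confidence))
  if (length(bad))
    stop("malformed edge rows in ", path, " at data lines: ",
         paste(head(bad, 10L), collapse = ", "))
  df
}

#' Write / read a localization TSV (gene, semicolon-joined labels)
#'
#' @param locmap named list gene -> character vector of labels.
#' @param path file path.
#' @export
write_localization_tsv <- function(locmap, path) {
  df <- data.frame(gene = names(locmap),
                   localizations = vapply(locmap, paste, character(1),
                                          collapse = ";"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_localization_tsv
#' @export
read_localization_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  setNames(strsplit(df$localizations, ";", fixed = TRUE), df$gene)
}

#' Write / read a GMT gene-set file
#'
#' Standard GMT grammar: one term per line, tab-separated name, description,
#' then member genes. The source tag is carried in the description field as
#' \code{source|name}.
#'
#' @param catalog a [gene_set_catalog()].
#' @param path file path.
#' @export
write_gmt <- function(catalog, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(catalog$term_id))
    writeLines(paste(c(catalog$term_id[i],
                       paste0(catalog$source[i], "|", catalog$term_name[i]),
                       catalog$genes[[i]]), collapse = "\t"),
               con, sep = "\n")
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("GMT lines need >= 3 fields (name, description, genes): ", path)
  desc <- vapply(parts, `[`, character(1), 2)
  has_src <- grepl("^(GO_BP|KEGG|other)\\|", desc)
  gene_set_catalog(
    term_id = vapply(parts, `[`, character(1), 1),
    term_name = ifelse(has_src, sub("^[^|]*\\|", "", desc), desc),
    source = ifelse(has_src, sub("\\|.*$", "", desc), "other"),
    genes = lapply(parts, function(p) p[-(1:2)]))
}

#' Export a network as SIF ("geneA pp geneB")
#'
#' @param network an igraph graph.
#' @param path file path.
#' @export
write_sif <- function(network, path) {
  el <- igraph::as_edgelist(network)
  writeLines(if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(),
             path)
  invisible(path)
}

#' Export a layered network as GraphML with tier coordinates
#'
#' Writes node attributes \code{layer}, \code{provenance}, \code{direction},
#' and display coordinates: y places plasma membrane on top and nucleus at
#' the bottom, x spreads nodes of a layer in deterministic (sorted id) order.
#'
#' @param layered a \code{layered_interactome}.
#' @param directions named character vector gene -> direction.
#' @param path file path.
#' @export
write_layered_graphml <- function(layered, directions, path) {
  g <- layered$network
  nm <- igraph::V(g)$name
  igraph::V(g)$layer <- unname(layered$layer[nm])
  igraph::V(g)$provenance <- unname(layered$provenance[nm])
  igraph::V(g)$direction <- unname(directions[nm])
  ypos <- c(plasma_membrane = 2, cytoplasm = 1, nucleus = 0)
  igraph::V(g)$y <- unname(ypos[layered$layer[nm]])
  x <- numeric(length(nm))
  for (l in CANONICAL_LAYERS) {
    i <- which(layered$layer[nm] == l)
    x[i][order(nm[i])] <- seq_along(i)
  }
  igraph::V(g)$x <- x
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a kappa graph as GraphML
#'
#' Node size encodes enrichment significance as -log10(adjusted p), clipped
#' to the display range [5e-2, 5e-6].
#'
#' @param kgraph a \code{kappa_graph}.
#' @param enriched the matching \code{enrichment_result}.
#' @param path file path.
#' @export
write_kappa_graphml <- function(kgraph, enriched, path) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(kgraph$nodes)
  if (nrow(kgraph$edges))
    g <- igraph::add_edges(g,
      rbind(match(kgraph$edges$a, kgraph$nodes),
            match(kgraph$edges$b, kgraph$nodes)),
      kappa = kgraph$edges$kappa)
  p <- enriched$p_bonferroni[match(kgraph$nodes, enriched$term_id)]
  p <- pmin(pmax(p, 5e-6), 5e-2)
  igraph::V(g)$size <- -log10(p)
  igraph::V(g)$p_bonferroni <- enriched$p_bonferroni[
    match(kgraph$nodes, enriched$term_id)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
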