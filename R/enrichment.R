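#' Upper-tail hypergeometric p-value
#'
#' P(X >= x) for X ~ hypergeometric(N, K, n): the over-representation p for
#' observing \code{x} hits when drawing \code{n} genes from a background of
#' \code{N} containing \code{K} term genes. Computed stably by summing
#' log-space binomial coefficients. The EASE-style variant scores
#' \code{x - 1} hits (more conservative for small counts), as popularised by
#' annotation servers.
#'
#' @param x observed hit count, \code{0 <= x <= min(K, n)}.
#' @param K term size within the background.
#' @param n query (draw) size.
#' @param N background size.
#' @param ease use the EASE-style penalised tail; default FALSE.
#' @return p-value in [0, 1].
#' @export
hypergeometric_pvalue <- function(x, K, n, N, ease = FALSE) {
  stopifnot(length(x) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N || x < 0 || x > min(K, n))
    stop("invalid hypergeometric parameters: x=", x, " K=", K, " n=", n, " N=", N)
  if (ease) x <- max(0L, x - 1L)
  if (x == 0) return(1)
  k <- x:min(K, n)
  lo <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  m <- max(lo)
  min(1, exp(m + log(sum(exp(lo - m)))))
}

#' Bonferroni adjustment
#'
#' @param p_raw raw p-value(s).
#' @param m number of tests, >= 1.
#' @return \code{min(1, m * p_raw)}.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(1, m * p_raw)
}

#' Per-layer gene-set over-representation
#'
#' Tests each catalog term for over-representation among one layer's genes
#' against a background set via the upper-tail hypergeometric. Terms with
#' fewer than \code{min_hits} hits are not tested and do not count toward the
#' Bonferroni family size \code{m}; \code{m} is the number of terms actually
#' tested in this layer. Returns the Bonferroni-significant terms sorted by
#' adjusted p then term id.
#'
#' @param layered a \code{layered_interactome} (or a named character vector
#'   node -> layer).
#' @param layer one canonical layer name.
#' @param catalog a \code{gene_set_catalog} as from [gene_set_catalog()].
#' @param background character vector of background gene ids (conventionally
#'   all genes on the expression matrix).
#' @param directions named character vector gene -> direction, used for
#'   \code{pct_up}.
#' @param alpha significance level on the Bonferroni-adjusted p; default 0.05.
#' @param min_hits minimum hit count for a term to be tested; default 2.
#' @param ease use the EASE-style tail; default FALSE.
#' @return data.frame (class \code{enrichment_result}) with columns term_id,
#'   term_name, source, layer, x, K, n, N, p_raw, p_bonferroni, pct_up,
#'   hit_genes (semicolon-joined). Attribute \code{m} holds the family size;
#'   attribute \code{tested} the full tested table before the alpha cut.
#' @export
enrich_layer <- function(layered, layer, catalog, background, directions,
                         alpha = 0.05, min_hits = 2, ease = FALSE) {
  stopifnot(min_hits >= 1, layer %in% CANONICAL_LAYERS)
  layer_map <- if (inherits(layered, "layered_interactome")) layered$layer else layered
  layer_genes <- names(layer_map)[layer_map == layer]
  if (!all(layer_genes %in% background))
    stop("layer genes must be a subset of the background")
  empty <- data.frame(term_id = character(), term_name = character(),
                      source = character(), layer = character(),
                      x = integer(), K = integer(), n = integer(), N = integer(),
                      p_raw = numeric(), p_bonferroni = numeric(),
                      pct_up = numeric(), hit_genes = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (!length(layer_genes)) {
    warning("empty layer: ", layer)
    attr(empty, "m") <- 0L
    return(empty)
  }
  N <- length(unique(background))
  n <- length(layer_genes)
  rows <- lapply(seq_along(catalog$term_id), function(i) {
    gs <- intersect(catalog$genes[[i]], background)
    hits <- intersect(gs, layer_genes)
    if (length(hits) < min_hits) return(NULL)
    p <- hypergeometric_pvalue(length(hits), length(gs), n, N, ease = ease)
    data.frame(term_id = catalog$term_id[i], term_name = catalog$term_name[i],
               source = catalog$source[i], layer = layer,
               x = length(hits), K = length(gs), n = n, N = N, p_raw = p,
               pct_up = mean(directions[hits] == "up"),
               hit_genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  m <- length(rows)
  if (!m) {
    attr(empty, "m") <- 0L
    return(empty)
  }
  tested <- do.call(rbind, rows)
  tested$p_bonferroni <- bonferroni(tested$p_raw, m)
  tested <- tested[order(tested$p_bonferroni, tested$term_id), ]
  tested <- tested[, c("term_id", "term_name", "source", "layer", "x", "K",
                       "n", "N", "p_raw", "p_bonferroni", "pct_up", "hit_genes")]
  rownames(tested) <- NULL
  out <- tested[tested$p_bonferroni < alpha, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "m") <- m
  attr(out, "tested") <- tested
  out
}
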