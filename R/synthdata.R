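#' Synthetic-data configuration
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a
#' two-condition expression experiment with a chosen fraction of DE genes at
#' a chosen effect size, a functional-coupling style interaction network with
#' planted dense modules, a three-layer localization map with an unannotated
#' fraction, and a gene-set catalog with terms planted to be enriched among
#' DE genes of a chosen layer and direction.
#'
#' Defaults describe a small but fully featured experiment: 400 genes, 6
#' replicates per condition, 25% DE genes shifted by 3 within-group standard
#' deviations, one planted up-regulated cytoplasm term of 8 genes in a
#' 60-term catalog.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per condition (>= 2; the t test needs a
#'   variance estimate).
#' @param de_fraction fraction of genes that are differentially expressed.
#' @param effect_size mean shift for DE genes in units of the within-group
#'   standard deviation.
#' @param up_fraction fraction of DE genes shifted up (higher in the
#'   reference group).
#' @param layer_proportions three fractions summing to 1 over
#'   plasma_membrane, cytoplasm, nucleus.
#' @param unannotated_fraction fraction of genes with no localization record.
#' @param n_terms total catalog size (planted terms included).
#' @param planted_terms list of specs, each a list with \code{layer},
#'   \code{direction} ("up"/"down"), \code{term_size}, \code{signal_genes}
#'   (how many members are drawn from DE genes of that layer and direction;
#'   must be a majority of \code{term_size}).
#' @param edge_density_background Erdős–Rényi background edge probability.
#' @param module_edge_density within-module edge probability for planted
#'   terms.
#' @param noise_sd within-group standard deviation of the Gaussian noise.
#' @param rng_seed integer seed; all randomness flows from it.
#' @return A validated \code{synth_config} list.
#' @export
synth_config <- function(n_genes = 400, n_per_group = 6, de_fraction = 0.25,
                         effect_size = 3, up_fraction = 0.5,
                         layer_proportions = c(plasma_membrane = 1/3,
                                               cytoplasm = 1/3, nucleus = 1/3),
                         unannotated_fraction = 0.1, n_terms = 60,
                         planted_terms = list(list(layer = "cytoplasm",
                                                   direction = "up",
                                                   term_size = 8,
                                                   signal_genes = 8)),
                         edge_density_background = 0.05,
                         module_edge_density = 0.8,
                         noise_sd = 1, rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
              de_fraction = de_fraction, effect_size = effect_size,
              up_fraction = up_fraction, layer_proportions = layer_proportions,
              unannotated_fraction = unannotated_fraction,
              n_terms = as.integer(n_terms), planted_terms = planted_terms,
              edge_density_background = edge_density_background,
              module_edge_density = module_edge_density,
              noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
  frac <- c(cfg$de_fraction, cfg$up_fraction, cfg$unannotated_fraction,
            cfg$edge_density_background, cfg$module_edge_density,
            cfg$layer_proportions)
  if (any(frac < 0 | frac > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(sum(cfg$layer_proportions) - 1) > 1e-9)
    stop("layer_proportions must sum to 1")
  if (!setequal(names(cfg$layer_proportions), CANONICAL_LAYERS))
    stop("layer_proportions must be named over the three canonical layers")
  if (cfg$n_per_group < 2L) stop("n_per_group must be >= 2")
  for (pt in cfg$planted_terms) {
    stopifnot(pt$layer %in% CANONICAL_LAYERS, pt$direction %in% c("up", "down"),
              pt$signal_genes <= pt$term_size)
  }
  class(cfg) <- "synth_config"
  cfg
}

# decode linear indices of the upper triangle of an n x n matrix
# (column-major over pairs i < j) into (i, j)
pair_from_index <- function(idx, n) {
  # j is the smallest integer with cumulative pair count >= idx
  cum <- cumsum(seq_len(n) - 1L)      # pairs ending at column j
  j <- findInterval(idx - 1L, cum) + 1L
  i <- idx - c(0L, cum)[j]
  cbind(i, j + 0L)
}

#' Simulate a complete synthetic input bundle
#'
#' Generates the four pipeline inputs plus the planted ground truth.
#' Expression is baseline + condition shift (effect_size * noise_sd for DE
#' genes, signed by direction, on the reference group) + i.i.d. Gaussian
#' noise. The network is an Erdős–Rényi background plus dense planted
#' modules over each planted term's signal genes; isolated nodes are then
#' connected to a random module node (or any random node when no module
#' exists). Identical configs reproduce identical outputs.
#'
#' @param config a [synth_config()].
#' @return list with \code{dataset} ([expression_dataset()]), \code{edges}
#'   (data.frame gene_a, gene_b, confidence), \code{locmap} (named list),
#'   \code{catalog} ([gene_set_catalog()]) and \code{truth} (list:
#'   \code{de_genes} named direction vector, \code{planted_term_ids}
#'   data.frame, \code{planted_module_edges}, \code{layer_truth}).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed)
  n <- config$n_genes
  genes <- sprintf("G%06d", seq_len(n))

  layer_truth <- setNames(
    sample(CANONICAL_LAYERS, n, replace = TRUE,
           prob = config$layer_proportions[CANONICAL_LAYERS]), genes)

  # DE assignment: planted-term signal genes first, then fill at random
  n_de <- round(config$de_fraction * n)
  n_up <- round(config$up_fraction * n_de)
  de_dir <- character(0)
  planted_members <- list()
  taken <- character(0)
  for (k in seq_along(config$planted_terms)) {
    pt <- config$planted_terms[[k]]
    pool <- setdiff(genes[layer_truth == pt$layer], taken)
    if (length(pool) < pt$signal_genes)
      stop("planted term needs ", pt$signal_genes, " ", pt$direction,
           "-regulated ", pt$layer, " genes but only ", length(pool),
           " are available")
    sig <- sample(pool, pt$signal_genes)
    de_dir <- c(de_dir, setNames(rep(pt$direction, length(sig)), sig))
    taken <- c(taken, sig)
    filler <- sample(setdiff(genes, taken), pt$term_size - pt$signal_genes)
    taken <- c(taken, filler)
    planted_members[[k]] <- c(sig, filler)
  }
  n_up_left <- n_up - sum(de_dir == "up")
  n_dn_left <- (n_de - n_up) - sum(de_dir == "down")
  if (n_up_left < 0 || n_dn_left < 0)
    stop("planted terms demand more DE genes of one direction than de_fraction/up_fraction allow")
  free <- setdiff(genes, names(de_dir))
  extra <- sample(free, n_up_left + n_dn_left)
  de_dir <- c(de_dir,
              setNames(rep(c("up", "down"), c(n_up_left, n_dn_left)), extra))
  if (length(de_dir)) de_dir <- de_dir[order(names(de_dir))]
  else de_dir <- setNames(character(0), character(0))

  # expression matrix
  ns <- config$n_per_group
  sample_ids <- c(sprintf("A%02d", seq_len(ns)), sprintf("B%02d", seq_len(ns)))
  condition <- factor(rep(c("groupA", "groupB"), each = ns),
                      levels = c("groupA", "groupB"))
  baseline <- rnorm(n, mean = 7, sd = 1)
  values <- baseline + matrix(rnorm(n * 2 * ns, sd = config$noise_sd),
                              nrow = n)
  if (length(de_dir)) {
    shift <- config$effect_size * config$noise_sd *
      ifelse(de_dir == "up", 1, -1)
    rows <- match(names(de_dir), genes)
    values[rows, seq_len(ns)] <- values[rows, seq_len(ns)] + shift
  }
  dataset <- expression_dataset(values, genes, sample_ids, condition)

  # catalog: planted terms first, background terms fill to n_terms
  n_planted <- length(config$planted_terms)
  if (config$n_terms < n_planted) stop("n_terms smaller than planted_terms")
  term_id <- sprintf("T%04d", seq_len(config$n_terms))
  term_genes <- vector("list", config$n_terms)
  src <- sample(c("GO_BP", "KEGG"), config$n_terms, replace = TRUE,
                prob = c(0.8, 0.2))
  for (k in seq_len(n_planted)) term_genes[[k]] <- planted_members[[k]]
  for (k in seq_len(config$n_terms)) {
    if (k <= n_planted) next
    sz <- sample(10:30, 1)
    term_genes[[k]] <- sample(genes, min(sz, n))
  }
  catalog <- gene_set_catalog(term_id,
                              term_name = paste("synthetic process", term_id),
                              source = src, genes = term_genes)

  # localization: drop unannotated fraction; labels are free text
  label_of <- c(plasma_membrane = "Plasma membrane", cytoplasm = "Cytoplasm",
                nucleus = "Nucleus")
  unann <- sample(genes, round(config$unannotated_fraction * n))
  locmap <- setNames(as.list(label_of[layer_truth[setdiff(genes, unann)]]),
                     setdiff(genes, unann))

  # network: ER background + planted dense modules + rescue of isolates
  npairs <- n * (n - 1) / 2
  m_bg <- rbinom(1, npairs, config$edge_density_background)
  idx <- sort(sample.int(npairs, m_bg))
  ij <- pair_from_index(idx, n)
  edges <- data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
                      confidence = round(runif(m_bg, 0.1, 1), 4),
                      stringsAsFactors = FALSE)
  module_edges <- data.frame(gene_a = character(), gene_b = character(),
                             confidence = numeric(), stringsAsFactors = FALSE)
  for (k in seq_len(n_planted)) {
    mem <- sort(planted_members[[k]])
    if (length(mem) < 2L) next
    pr <- t(utils::combn(mem, 2))
    keep <- runif(nrow(pr)) < config$module_edge_density
    if (!any(keep)) next
    module_edges <- rbind(module_edges,
      data.frame(gene_a = pr[keep, 1], gene_b = pr[keep, 2],
                 confidence = round(runif(sum(keep), 0.7, 1), 4),
                 stringsAsFactors = FALSE))
  }
  edges <- rbind(edges, module_edges)
  touched <- unique(c(edges$gene_a, edges$gene_b))
  isolated <- setdiff(genes, touched)
  if (length(isolated)) {
    anchor_pool <- if (nrow(module_edges))
      unique(c(module_edges$gene_a, module_edges$gene_b)) else genes
    anchors <- sample(anchor_pool, length(isolated), replace = TRUE)
    self <- anchors == isolated
    if (any(self)) anchors[self] <- sample(setdiff(anchor_pool, isolated[self]),
                                           sum(self), replace = TRUE)
    edges <- rbind(edges, data.frame(gene_a = isolated, gene_b = anchors,
                                     confidence = round(runif(length(isolated),
                                                              0.1, 1), 4),
                                     stringsAsFactors = FALSE))
  }
  # collapse duplicates (module edges may repeat background pairs), max conf
  lo <- pmin(edges$gene_a, edges$gene_b); hi <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(lo, hi, sep = "\r")
  o <- order(key, -edges$confidence)
  first <- !duplicated(key[o])
  edges <- data.frame(gene_a = lo[o][first], gene_b = hi[o][first],
                      confidence = edges$confidence[o][first],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  rownames(edges) <- NULL

  truth <- list(
    de_genes = de_dir,
    planted_term_ids = if (n_planted) data.frame(
      term_id = term_id[seq_len(n_planted)],
      layer = vapply(config$planted_terms, `[[`, character(1), "layer"),
      direction = vapply(config$planted_terms, `[[`, character(1), "direction"),
      stringsAsFactors = FALSE)
    else data.frame(term_id = character(), layer = character(),
                    direction = character(), stringsAsFactors = FALSE),
    planted_module_edges = module_edges,
    layer_truth = layer_truth)

  list(dataset = dataset, edges = edges, locmap = locmap, catalog = catalog,
       truth = truth)
}

#' Write a simulated bundle to fixture files
#'
#' Emits expression TSV, edge-list TSV, localization TSV and GMT catalog
#' into \code{dir}, plus a JSON manifest listing paths and md5 content
#' hashes.
#'
#' @param bundle result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (the manifest contents), invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             edges = file.path(dir, "edges.tsv"),
             localization = file.path(dir, "localization.tsv"),
             catalog = file.path(dir, "catalog.gmt"))
  ok <- try({
    write_expression_tsv(bundle$dataset, paths[["expression"]])
    write_edge_tsv(bundle$edges, paths[["edges"]])
    write_localization_tsv(bundle$locmap, paths[["localization"]])
    write_gmt(bundle$catalog, paths[["catalog"]])
  }, silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed writing fixtures under ", dir, ": ", attr(ok, "condition")$message)
  manifest <- list(files = as.list(paths),
                   md5 = as.list(unname(tools::md5sum(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
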