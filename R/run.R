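#' Run the full pipeline from a config
#'
#' Single entry point behind the analysis: loads the four inputs (from files,
#' or by simulation when the config has a \code{synthetic} block), runs
#' [layint()], and optionally writes all stage artifacts plus a structured
#' JSON report. Identical config and seed give a byte-identical report:
#' every tie-break in the pipeline is deterministic and all randomness flows
#' from \code{rng_seed}.
#'
#' @param config a list, or the path of a YAML file holding one. Recognised
#'   blocks: \code{synthetic} (arguments of [synth_config()]) \emph{or}
#'   \code{files} (paths \code{expression}, \code{edges},
#'   \code{localization}, \code{catalog}); \code{control} (arguments of
#'   [layint_control()]); optional \code{seeds} (gene ids or
#'   \code{"term:<id>"}); optional \code{rng_seed} (overrides the synthetic
#'   block's seed).
#' @param out_dir optional output directory for stage TSVs, GraphML exports
#'   and \code{report.json}.
#' @return invisibly, a list with \code{fit} (the [layint()] object) and
#'   \code{report} (the report list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  control <- do.call(layint_control, config$control %||% list())
  input_hashes <- NULL
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (!is.null(config$rng_seed)) args$rng_seed <- config$rng_seed
    if (!is.null(args$layer_proportions))
      args$layer_proportions <- unlist(args$layer_proportions)
    scfg <- do.call(synth_config, args)
    bundle <- with_stage("synthdata", simulate_dataset(scfg))
  } else if (!is.null(config$files)) {
    f <- config$files
    for (p in unlist(f)) if (!file.exists(p)) stop("input file not found: ", p)
    bundle <- with_stage("input", list(
      dataset = read_expression_tsv(f$expression),
      edges = read_edge_tsv(f$edges),
      locmap = read_localization_tsv(f$localization),
      catalog = read_gmt(f$catalog)))
    input_hashes <- as.list(tools::md5sum(unlist(f)))
  } else stop("config needs a 'synthetic' or a 'files' block")

  fit <- layint(bundle$dataset, bundle$edges, bundle$locmap, bundle$catalog,
                control = control, seeds = config$seeds)

  report <- pipeline_report(fit, config, input_hashes)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(fit$de, file.path(out_dir, "de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (igraph::vcount(fit$network) > 0) {
      el <- igraph::as_data_frame(fit$network, what = "edges")
      write_edge_tsv(data.frame(gene_a = el$from, gene_b = el$to,
                                confidence = el$weight),
                     file.path(out_dir, "network.tsv"))
      write_sif(fit$network, file.path(out_dir, "network.sif"))
    }
    if (!is.null(fit$layered)) {
      nodes <- names(fit$layered$layer)
      write.table(data.frame(gene = nodes,
                             layer = unname(fit$layered$layer),
                             provenance = unname(fit$layered$provenance),
                             direction = unname(fit$directions[nodes])),
                  file.path(out_dir, "nodes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_layered_graphml(fit$layered, fit$directions,
                            file.path(out_dir, "network.graphml"))
    }
    enr <- do.call(rbind, Filter(function(e) !is.null(e) && nrow(e),
                                 fit$enrichment))
    if (!is.null(enr) && nrow(enr))
      write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write.table(groups_table(fit), file.path(out_dir, "groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (l in names(fit$kappa_graphs))
      write_kappa_graphml(fit$kappa_graphs[[l]], fit$enrichment[[l]],
                          file.path(out_dir, paste0("kappa_", l, ".graphml")))
    if (!is.null(fit$seednet))
      write.table(fit$seednet$members, file.path(out_dir, "seednet.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(fit = fit, report = report))
}

# structured, JSON-serialisable summary of a fit; every number is
# recomputable from the stage outputs
pipeline_report <- function(fit, config, input_hashes = NULL) {
  gt <- groups_table(fit)
  list(
    de = fit$counts[c("de_total", "de_up", "de_down", "de_unclustered")],
    network = fit$counts[c("network_nodes_prefilter",
                           "network_edges_prefilter",
                           "network_nodes", "network_edges")],
    table1 = render_table1(fit),
    enrichment = lapply(fit$enrichment, function(e) {
      if (is.null(e)) return(list(m = 0, significant = 0))
      list(m = attr(e, "m") %||% 0L, significant = nrow(e),
           terms = e$term_id)
    }),
    groups = if (nrow(gt)) gt[, setdiff(names(gt), "members")] else list(),
    seednet = if (!is.null(fit$seednet))
      list(seeds = fit$seednet$seeds,
           core = fit$seednet$members$gene[fit$seednet$members$tier == "core"],
           n_members = nrow(fit$seednet$members)) else NULL,
    config = config,
    input_hashes = input_hashes,
    enrichment_variant = if (isTRUE(fit$control$ease)) "ease" else
      "hypergeometric")
}
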