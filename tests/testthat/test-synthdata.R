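test_that("config invariants are enforced", {
  expect_error(synth_config(n_per_group = 1), "n_per_group")
  expect_error(synth_config(layer_proportions = c(plasma_membrane = 0.5,
                                                  cytoplasm = 0.5,
                                                  nucleus = 0.5)), "sum to 1")
  expect_error(synth_config(de_fraction = 1.2), "fractions")
  # planted term demanding more genes than a layer can hold
  cfg <- synth_config(n_genes = 20,
                      planted_terms = list(list(layer = "nucleus",
                                                direction = "up",
                                                term_size = 19,
                                                signal_genes = 19)))
  expect_error(simulate_dataset(cfg), "available|allow")
})

test_that("no planted effect means empty DE truth; seeded runs are identical", {
  cfg <- synth_config(n_genes = 100, de_fraction = 0, planted_terms = list(),
                      rng_seed = 5)
  b <- simulate_dataset(cfg)
  expect_length(b$truth$de_genes, 0)
  b2 <- simulate_dataset(cfg)
  expect_identical(b$dataset$values, b2$dataset$values)
  expect_identical(b$edges, b2$edges)
  expect_identical(b$catalog$genes, b2$catalog$genes)
  expect_identical(b$locmap, b2$locmap)
})

test_that("null simulation yields a binomial number of t-test positives", {
  # 1000 null genes at alpha 0.05: count within 50 +/- 3*sqrt(1000*.05*.95)
  cfg <- synth_config(n_genes = 1000, de_fraction = 0, effect_size = 0,
                      planted_terms = list(), rng_seed = 104)
  b <- simulate_dataset(cfg)
  de <- suppressMessages(select_de_genes(b$dataset, 0.05))
  n_de <- sum(de$p_value < 0.05)
  expect_lt(abs(n_de - 50), 3 * sqrt(1000 * 0.05 * 0.95))
})

test_that("planted DE genes carry the configured shift and direction", {
  cfg <- synth_config(rng_seed = 3)
  b <- simulate_dataset(cfg)
  expect_true(all(names(b$truth$de_genes) %in% b$dataset$gene_ids))
  de <- suppressMessages(select_de_genes(b$dataset, 0.05))
  md <- setNames(de$mean_diff, de$gene)[names(b$truth$de_genes)]
  # 3 sigma shifts at n=6 essentially always land on the planted side
  expect_gt(mean(sign(md) == ifelse(b$truth$de_genes == "up", 1, -1)), 0.99)
})

test_that("planted genes pass the t test in >= 95% of seeded replicates", {
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    cfg <- synth_config(n_genes = 60, de_fraction = 0.2, effect_size = 3,
                        n_per_group = 6,
                        planted_terms = list(list(layer = "cytoplasm",
                                                  direction = "up",
                                                  term_size = 5,
                                                  signal_genes = 5)),
                        rng_seed = 7000 + s)
    b <- simulate_dataset(cfg)
    de <- suppressMessages(select_de_genes(b$dataset, 0.05))
    p <- setNames(de$p_value, de$gene)[names(b$truth$de_genes)]
    hits <- hits + sum(p < 0.05); total <- total + length(p)
  }
  expect_gte(hits / total, 0.95)
})

test_that("planted term layers equal the modal truth layer of their members", {
  b <- simulate_dataset(synth_config(rng_seed = 12, planted_terms = list(
    list(layer = "nucleus", direction = "down", term_size = 10,
         signal_genes = 8),
    list(layer = "cytoplasm", direction = "up", term_size = 8,
         signal_genes = 8))))
  for (i in seq_len(nrow(b$truth$planted_term_ids))) {
    tid <- b$truth$planted_term_ids$term_id[i]
    mem <- b$catalog$genes[[match(tid, b$catalog$term_id)]]
    modal <- names(which.max(table(b$truth$layer_truth[mem])))
    expect_equal(modal, b$truth$planted_term_ids$layer[i])
  }
})

test_that("generated network connects every gene and contains the module", {
  b <- simulate_dataset(synth_config(rng_seed = 2))
  g <- igraph::graph_from_data_frame(
    b$edges[, c("gene_a", "gene_b")], directed = FALSE)
  expect_setequal(igraph::V(g)$name, b$dataset$gene_ids)  # no isolated genes
  # no self-loops or duplicate unordered pairs in the emitted edge list
  expect_true(all(b$edges$gene_a != b$edges$gene_b))
  key <- paste(pmin(b$edges$gene_a, b$edges$gene_b),
               pmax(b$edges$gene_a, b$edges$gene_b))
  expect_false(any(duplicated(key)))
  expect_gt(nrow(b$truth$planted_module_edges), 0)
})
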