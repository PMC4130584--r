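test_that("hypergeometric tail matches exact enumeration and closed forms", {
  # all 5 term genes drawn in a 5-gene query from 10: C(5,5)/C(10,5) = 1/252
  expect_equal(hypergeometric_pvalue(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeometric_pvalue(0, 5, 5, 10), 1)
  expect_equal(hypergeometric_pvalue(4, 4, 4, 4), 1)
  expect_error(hypergeometric_pvalue(6, 5, 5, 10), "invalid")
  # stats::phyper as an independent cross-check on larger parameters
  expect_equal(hypergeometric_pvalue(12, 40, 60, 400),
               phyper(11, 40, 360, 60, lower.tail = FALSE), tolerance = 1e-12)
  # EASE-style variant scores x - 1
  expect_equal(hypergeometric_pvalue(5, 5, 5, 10, ease = TRUE),
               hypergeometric_pvalue(4, 5, 5, 10))
})

test_that("tail probability is non-increasing in x and monotone sane", {
  p <- vapply(0:8, function(x) hypergeometric_pvalue(x, 10, 8, 30), numeric(1))
  expect_true(all(diff(p) <= 1e-14))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(2e-6, 100), 2e-4)
  expect_error(bonferroni(0.1, 0))
})

# a tiny layered universe: 10 genes, layer holds g1..g5
tiny_layered <- function() {
  genes <- sprintf("g%02d", 1:10)
  layer <- setNames(c(rep("cytoplasm", 5), rep("nucleus", 5)), genes)
  dirs <- setNames(rep(c("up", "down"), 5), genes)
  list(genes = genes, layer = layer, dirs = dirs)
}

test_that("enrich_layer composes the oracles and applies its filters", {
  u <- tiny_layered()
  cat <- gene_set_catalog(c("hit", "single", "everything"),
                          genes = list(sprintf("g%02d", 1:5), "g01", u$genes))
  res <- enrich_layer(u$layer, "cytoplasm", cat, u$genes, u$dirs,
                      alpha = 0.05, min_hits = 2)
  # the planted term: x=K=n=5, N=10 -> p_raw 1/252; m = 2 tested terms
  expect_equal(attr(res, "m"), 2L)
  expect_true("hit" %in% res$term_id)
  hit <- res[res$term_id == "hit", ]
  expect_equal(hit$p_raw, 1 / 252, tolerance = 1e-12)
  expect_equal(hit$p_bonferroni, 2 / 252, tolerance = 1e-12)
  expect_equal(hit$x, 5L)
  expect_equal(hit$pct_up, 3 / 5)
  # single-hit term is neither tested nor counted in m
  expect_false("single" %in% attr(res, "tested")$term_id)
  # whole-background term: p_raw = 1, never significant
  tested <- attr(res, "tested")
  expect_equal(tested$p_raw[tested$term_id == "everything"], 1)
  expect_false("everything" %in% res$term_id)
})

test_that("enrich_layer rejects layer genes outside the background", {
  u <- tiny_layered()
  cat <- gene_set_catalog("t", genes = list(c("g01", "g02")))
  expect_error(enrich_layer(u$layer, "cytoplasm", cat, u$genes[-1], u$dirs),
               "background")
  expect_warning(
    enrich_layer(u$layer, "plasma_membrane", cat, u$genes, u$dirs),
    "empty layer")
})

test_that("hypergeometric equals exhaustive enumeration for N <= 12", {
  for (N in c(6, 9, 12)) for (K in c(2, N %/% 2)) for (n in c(2, N %/% 2)) {
    for (x in 0:min(K, n)) {
      expect_equal(hypergeometric_pvalue(x, K, n, N),
                   enum_hyper_tail(x, K, n, N), tolerance = 1e-10,
                   info = sprintf("x=%d K=%d n=%d N=%d", x, K, n, N))
    }
  }
})

test_that("empirical permutation p agrees with the analytic tail", {
  set.seed(99)
  N <- 40; K <- 12; n <- 10; x <- 5
  draws <- replicate(20000, sum(sample.int(N, n) <= K))
  emp <- mean(draws >= x)
  p <- hypergeometric_pvalue(x, K, n, N)
  mc_se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(emp - p), 3 * mc_se)
})

test_that("null enrichment keeps family-wise error at or below alpha", {
  set.seed(17)
  genes <- sprintf("g%03d", 1:200)
  cat <- random_catalog(genes, 50)
  any_sig <- replicate(100, {
    layer <- setNames(rep("nucleus", 30), sample(genes, 30))
    dirs <- setNames(sample(c("up", "down"), 200, TRUE), genes)
    r <- enrich_layer(layer, "nucleus", cat, genes, dirs, alpha = 0.05)
    nrow(r) > 0
  })
  expect_lte(mean(any_sig), 0.05)
})
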