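test_that("pooled-variance t test matches closed form and handles degeneracies", {
  ds <- toy_dataset(rbind(g1 = c(1, 2, 3, 1, 2, 3),
                          g2 = c(1, 2, 3, 3, 4, 5),
                          g3 = c(2, 2, 2, 5, 5, 5)))
  # identical groups
  r <- student_t_test(ds, "g1")
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  # hand-computed pooled t: t = -2/sqrt(1 * 2/3), df = 4
  r <- student_t_test(ds, "g2")
  expect_equal(r$t_statistic, -2 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$p_value, 2 * pt(-2 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(r$p_value, 0.0705, tolerance = 5e-3)
  # zero pooled variance, unequal means
  r <- student_t_test(ds, "g3")
  expect_equal(r$p_value, 0)
  expect_error(student_t_test(ds, "nope"), "not found")
})

test_that("t test agrees with stats::t.test on random data", {
  set.seed(11)
  vals <- matrix(rnorm(20 * 10), 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  ds <- toy_dataset(vals, n_a = 5, n_b = 5)
  for (g in c("g01", "g07", "g20")) {
    ref <- t.test(vals[g, 1:5], vals[g, 6:10], var.equal = TRUE)
    r <- student_t_test(ds, g)
    expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("select_de_genes flags by raw p and respects the alpha limit", {
  set.seed(3)
  vals <- matrix(rnorm(200 * 8), 200,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  ds <- toy_dataset(vals, n_a = 4, n_b = 4)
  de <- suppressMessages(select_de_genes(ds, alpha = 0.05))
  expect_true(all((de$direction != "not_de") == (de$p_value < 0.05)))
  # alpha -> 1: effectively everything flagged
  de1 <- suppressMessages(select_de_genes(ds, alpha = 0.999999))
  expect_gt(mean(de1$direction != "not_de"), 0.99)
  expect_error(select_de_genes(ds, alpha = 0))
})

test_that("direction clustering recovers planted directions and the floor rule", {
  ds <- direction_fixture()
  de <- suppressMessages(select_de_genes(ds, alpha = 0.25))
  de <- cluster_directions(ds, de)
  expect_equal(de$direction[1:6], rep("up", 6))
  expect_equal(de$direction[7:12], rep("down", 6))
  # the odd gene is DE but anti-correlated with its own cluster centroid
  expect_equal(de$direction[13], "unclustered")
  # partition property: up/down/unclustered tile the DE set exactly
  expect_setequal(which(de$direction != "not_de"), 1:13)
})

test_that("swapping condition labels swaps directions and negates mean_diff", {
  ds <- direction_fixture()
  ds2 <- expression_dataset(ds$values, sample_ids = ds$sample_ids,
                            condition = factor(ds$condition,
                                               levels = rev(levels(ds$condition))))
  de1 <- cluster_directions(ds, suppressMessages(select_de_genes(ds, 0.25)))
  de2 <- cluster_directions(ds2, suppressMessages(select_de_genes(ds2, 0.25)))
  expect_equal(de1$p_value, de2$p_value)
  expect_equal(de1$mean_diff, -de2$mean_diff)
  flip <- c(up = "down", down = "up", unclustered = "unclustered",
            not_de = "not_de")
  expect_equal(unname(flip[de1$direction]), de2$direction)
})

test_that("noiseless data: cluster labels equal the sign of mean_diff", {
  up <- c(8, 8, 8, 4, 4, 4); dn <- c(3, 3, 3, 9, 9, 9)
  vals <- rbind(matrix(rep(up, 4), 4, byrow = TRUE),
                matrix(rep(dn, 3), 3, byrow = TRUE))
  rownames(vals) <- sprintf("g%d", 1:7)
  ds <- toy_dataset(vals)
  de <- cluster_directions(ds, suppressMessages(select_de_genes(ds, 0.05)))
  expect_equal(de$direction, ifelse(de$mean_diff > 0, "up", "down"))
})

test_that("fewer than two DE genes fall back to the sign of mean_diff", {
  vals <- rbind(g1 = c(9, 9.1, 9, 4, 4.1, 4),
                g2 = c(5, 1, 8, 3, 9, 2))
  ds <- toy_dataset(vals)
  de <- cluster_directions(ds, suppressMessages(select_de_genes(ds, 0.01)))
  expect_equal(de$direction, c("up", "not_de"))
})
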