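test_that("kappa matches hand contingency values", {
  R <- sprintf("g%d", 1:10)
  expect_equal(kappa_score(R[1:4], R[1:4], R), 1)
  # a=2, b=2, c=2, d=4: po=0.6, pe=0.52 -> 1/6
  expect_equal(kappa_score(R[1:4], R[3:6], R), 1 / 6, tolerance = 1e-12)
  # complementary halves: perfect disagreement
  expect_equal(kappa_score(R[1:5], R[6:10], R), -1)
  expect_error(kappa_score(c("zz"), R[1:2], R), "subset")
  expect_error(kappa_score("g1", "g1", "g1"), "at least 2")
})

test_that("kappa degenerate conventions and symmetry/self properties", {
  R <- sprintf("g%d", 1:8)
  # both memberships constant (everything / everything): pe = 1
  expect_equal(kappa_score(R, R, R), 1)
  expect_equal(kappa_score(R, character(0), R), 0)
  set.seed(21)
  for (i in 1:50) {
    A <- sample(R, sample(0:8, 1))
    B <- sample(R, sample(0:8, 1))
    expect_equal(kappa_score(A, B, R), kappa_score(B, A, R))
    expect_equal(kappa_score(A, B, R), hand_kappa(A, B, R), tolerance = 1e-12)
    if (length(A) > 0 && length(A) < 8)
      expect_equal(kappa_score(A, A, R), 1)
  }
})

make_enr <- function(ids, hits, p = seq_along(ids) / 100, pct_up = 1) {
  structure(data.frame(term_id = ids, term_name = ids, source = "GO_BP",
                       layer = "cytoplasm", x = lengths(hits),
                       K = lengths(hits), n = 10, N = 20,
                       p_raw = p / 10, p_bonferroni = p,
                       pct_up = rep_len(pct_up, length(ids)),
                       hit_genes = vapply(hits, paste, "", collapse = ";"),
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

test_that("kappa graph edges follow the strict threshold", {
  R <- sprintf("g%d", 1:10)
  enr <- make_enr(c("TA", "TB", "TC"),
                  list(R[1:4], R[3:6], R[3:6]))
  kg <- build_kappa_graph(enr, R, threshold = 0.3)
  # TA-TB kappa is 1/6 < 0.3: no edge; TB-TC identical: kappa 1
  expect_equal(nrow(kg$edges), 1L)
  expect_setequal(c(kg$edges$a, kg$edges$b), c("TB", "TC"))
  expect_equal(kg$edges$kappa, 1)
  kg2 <- build_kappa_graph(enr, R, threshold = 0.1)
  expect_equal(nrow(kg2$edges), 3L)   # 1/6 > 0.1 now links TA too
  # strictness: threshold exactly 1/6 still excludes the 1/6 pair
  kg3 <- build_kappa_graph(enr, R, threshold = 1 / 6)
  expect_equal(nrow(kg3$edges), 1L)
})

test_that("merge_groups: neighborhood seeds, share rule, fixed point", {
  R <- sprintf("g%d", 1:12)
  # path graph T1 - T2 - T3 via overlapping hit sets
  enr <- make_enr(c("T1", "T2", "T3"),
                  list(R[1:4], R[2:5], R[3:6]))
  kg <- build_kappa_graph(enr, R, threshold = 0.3)
  expect_setequal(paste(kg$edges$a, kg$edges$b),
                  c("T1 T2", "T2 T3"))
  groups <- merge_groups(kg, share_threshold = 0.5)
  # brute-force expectation: {T1,T2},{T1,T2,T3},{T2,T3} all merge into one
  expect_length(groups, 1L)
  expect_setequal(groups[[1]], c("T1", "T2", "T3"))

  # disconnected terms with no shared members stay separate
  enr2 <- make_enr(c("TA", "TB", "TC", "TD"),
                   list(R[1:3], R[1:3], R[7:9], R[7:9]))
  kg2 <- build_kappa_graph(enr2, R, threshold = 0.3)
  g2 <- merge_groups(kg2)
  expect_length(g2, 2L)
  expect_setequal(g2[[1]], c("TA", "TB"))
  expect_setequal(g2[[2]], c("TC", "TD"))

  # singleton (edge-less) terms form their own groups
  enr3 <- make_enr(c("TA", "TB"), list(R[1:3], R[8:12]))
  g3 <- merge_groups(build_kappa_graph(enr3, R))
  expect_length(g3, 2L)
})

test_that("merge fixed point: no two final groups share >= the threshold", {
  set.seed(31)
  R <- sprintf("g%d", 1:15)
  for (rep in 1:10) {
    ids <- sprintf("T%d", 1:8)
    hits <- lapply(1:8, function(i) sample(R, sample(2:6, 1)))
    kg <- build_kappa_graph(make_enr(ids, hits), R, threshold = 0.3)
    gr <- merge_groups(kg, share_threshold = 0.5)
    if (length(gr) >= 2) {
      for (i in 1:(length(gr) - 1)) for (j in (i + 1):length(gr)) {
        share <- length(intersect(gr[[i]], gr[[j]])) /
          min(length(gr[[i]]), length(gr[[j]]))
        expect_lt(share, 0.5)
      }
    }
    # order invariance of the input terms
    o <- sample(8)
    kg2 <- build_kappa_graph(make_enr(ids[o], hits[o]), R, threshold = 0.3)
    gr2 <- merge_groups(kg2, share_threshold = 0.5)
    norm <- function(g) sort(vapply(g, function(x) paste(sort(x), collapse = ","),
                                    ""))
    expect_equal(norm(gr), norm(gr2))
  }
})

test_that("group labels pick the minimum-p term per direction; pooled direction", {
  R <- sprintf("g%d", 1:10)
  # two up terms with p 0.0250 and 0.0156: label is the smaller-p term
  enr <- make_enr(c("golgi", "autophagosome"), list(R[1:4], R[2:5]),
                  p = c(0.015571, 0.025024), pct_up = 1)
  grp <- label_and_direct(c("golgi", "autophagosome"), enr,
                          setNames(rep("up", 10), R))
  expect_equal(grp$label_terms, "golgi")
  expect_equal(grp$direction, "up")
  expect_equal(grp$leading_p_bonferroni, 0.015571)

  # term typing at the 60% threshold: 4 up / 1 down -> up; 3/3 -> mixed
  dirs <- setNames(c(rep("up", 4), "down", rep("down", 3), rep("up", 2)), R)
  enr2 <- make_enr(c("T1", "T2"), list(R[1:5], R[c(1:3, 6:8)]),
                   p = c(0.01, 0.02), pct_up = c(0.8, 0.5))
  g1 <- label_and_direct("T1", enr2, dirs)
  expect_equal(unname(g1$term_directions), "up")
  g2 <- label_and_direct("T2", enr2, dirs)
  expect_equal(unname(g2$term_directions), "mixed")
  expect_equal(g2$direction, "mixed")
  # both directions present among members: both label terms reported
  dirs3 <- setNames(c(rep("up", 5), rep("down", 5)), R)
  enr3 <- make_enr(c("U", "D"), list(R[1:4], R[6:9]),
                   p = c(0.01, 0.002), pct_up = c(1, 0))
  g3 <- label_and_direct(c("U", "D"), enr3, dirs3)
  expect_setequal(g3$label_terms, c("U", "D"))
})
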