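# small in-code fixtures shared across tests

# expression set from two group-value vectors replicated over genes
toy_dataset <- function(values, n_a = 3, n_b = 3) {
  expression_dataset(values,
                     sample_ids = c(sprintf("a%d", seq_len(n_a)),
                                    sprintf("b%d", seq_len(n_b))),
                     condition = rep(c("grpA", "grpB"), c(n_a, n_b)))
}

# 6 coherent up genes, 6 mirrored down genes, 1 gene anti-correlated with
# both families (profiles = contrast +/- a shared within-group zig)
direction_fixture <- function() {
  con <- c(1, 1, 1, -1, -1, -1)
  zig <- c(2, -2, 0, 2, -2, 0)
  up <- 2.3 * con + 2 * zig + 8
  dn <- -2.3 * con + 2 * zig + 8
  w  <- 2.25 * con - 2 * zig + 8
  vals <- rbind(matrix(rep(up, 6), 6, byrow = TRUE),
                matrix(rep(dn, 6), 6, byrow = TRUE), w)
  rownames(vals) <- sprintf("g%02d", seq_len(13))
  toy_dataset(vals)
}

# undirected igraph from an edge matrix/data.frame of id pairs
toy_graph <- function(pairs, weights = rep(1, nrow(pairs))) {
  igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2], weight = weights),
    directed = FALSE)
}

# brute-force upper-tail hypergeometric by exhaustive enumeration of all
# C(N, n) query sets (oracle; independent of the package implementation)
enum_hyper_tail <- function(x, K, n, N) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  qs <- utils::combn(N, n)
  hits <- colSums(matrix(qs %in% inset, nrow = n))
  mean(hits >= x)
}

# hand contingency-table kappa (oracle)
hand_kappa <- function(A, B, R) {
  N <- length(R)
  a <- length(intersect(A, B)); b <- length(setdiff(A, B))
  c_ <- length(setdiff(B, A)); d <- N - a - b - c_
  po <- (a + d) / N
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / N^2
  if (abs(1 - pe) < 1e-12) return(if (b == 0 && c_ == 0) 1 else 0)
  (po - pe) / (1 - pe)
}

# catalog of random background terms over a gene universe
random_catalog <- function(genes, n_terms, sizes = 10:30) {
  gene_set_catalog(sprintf("T%04d", seq_len(n_terms)),
                   genes = lapply(seq_len(n_terms), function(i)
                     sample(genes, min(sample(sizes, 1), length(genes)))))
}
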