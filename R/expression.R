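#' Expression dataset constructor
#'
#' Bundles a gene-by-sample expression matrix with a two-level condition
#' factor. The first condition level is the reference group: "up" throughout
#' the package means higher expression in that group.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (row names).
#' @param sample_ids character vector of unique sample identifiers.
#' @param condition character or factor of length \code{ncol(values)} with
#'   exactly two levels; the first level is the reference (direction "up"
#'   means higher there). If character, level order is order of appearance.
#' @return An object of class \code{"expression_dataset"}.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values), condition) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("matrix dimensions do not match id lists")
  if (!is.factor(condition)) condition <- factor(condition, levels = unique(condition))
  condition <- droplevels(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels")
  if (length(condition) != length(sample_ids))
    stop("condition length must equal the number of samples")
  if (any(table(condition) < 2L))
    stop("both condition levels need at least 2 samples")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 condition = condition),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tb <- table(x$condition)
  cat(sprintf("expression_dataset: %d genes x %d samples (%s: %d, %s: %d)\n",
              nrow(x$values), ncol(x$values),
              levels(x$condition)[1], tb[1], levels(x$condition)[2], tb[2]))
  invisible(x)
}

# vectorized pooled-variance two-sample t over all genes;
# returns data.frame(gene, t, p_value, mean_diff)
# degenerate zero pooled variance: equal means -> t = 0, p = 1;
# unequal means -> p = 0 (t carries the sign of the difference)
t_test_all <- function(dataset) {
  ga <- dataset$condition == levels(dataset$condition)[1]
  a <- dataset$values[, ga, drop = FALSE]
  b <- dataset$values[, !ga, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  diff <- ma - mb
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- diff / se
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  deg <- se == 0
  if (any(deg)) {
    eq <- deg & diff == 0
    t[eq] <- 0; p[eq] <- 1
    ne <- deg & diff != 0
    t[ne] <- sign(diff[ne]) * Inf; p[ne] <- 0
  }
  data.frame(gene = dataset$gene_ids, t = unname(t), p_value = unname(p),
             mean_diff = unname(diff), stringsAsFactors = FALSE)
}

#' Two-sample Student's t test for one gene
#'
#' Two-sided, pooled-variance (equal-variance) test with
#' \code{nA + nB - 2} degrees of freedom. When the pooled variance is zero
#' the convention is \code{t = 0, p = 1} for equal group means and
#' \code{p = 0} otherwise.
#'
#' @param dataset an [expression_dataset()].
#' @param gene a gene id present in the dataset.
#' @return list with \code{t_statistic} and \code{p_value}.
#' @export
student_t_test <- function(dataset, gene) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!gene %in% dataset$gene_ids) stop("gene not found: ", gene)
  res <- t_test_all(dataset)
  i <- match(gene, res$gene)
  list(t_statistic = res$t[i], p_value = res$p_value[i])
}

#' Select differentially expressed genes
#'
#' Flags genes with raw two-sided t-test p below \code{alpha}. No multiplicity
#' correction is applied at this stage; family-wise control enters only at the
#' annotation-term level. DE genes are provisionally labelled
#' \code{"unclustered"} until [cluster_directions()] assigns up/down.
#'
#' @param dataset an [expression_dataset()].
#' @param alpha significance level in (0, 1); default 0.05.
#' @return A \code{differential_result} data.frame with columns gene, t,
#'   p_value, mean_diff, direction (\code{up}, \code{down},
#'   \code{unclustered} or \code{not_de}).
#' @export
select_de_genes <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "expression_dataset"), alpha > 0, alpha < 1)
  res <- t_test_all(dataset)
  res$direction <- ifelse(res$p_value < alpha, "unclustered", "not_de")
  attr(res, "alpha") <- alpha
  class(res) <- c("differential_result", "data.frame")
  message(sprintf("%d of %d genes differentially expressed at alpha = %g",
                  sum(res$p_value < alpha), nrow(res), alpha))
  res
}

#' Split DE genes into up- and down-regulated clusters
#'
#' Deterministic 2-medoid partitioning of the DE genes' standardized
#' expression profiles (per-gene z-scores across samples) under correlation
#' distance, seeded from the two genes with the most extreme mean difference.
#' Clusters are labelled up/down by the sign of their centroid's mean contrast
#' (reference group minus other group). DE genes whose profile correlation
#' with their own cluster centroid does not exceed \code{floor} are labelled
#' \code{"unclustered"}. With fewer than two DE genes, or for zero-variance
#' profiles, direction falls back to the sign of \code{mean_diff}.
#'
#' This replaces a heavier graph-theoretic expression clusterer: the only
#' observable it must reproduce is a split of the DE set into two directed
#' clusters plus a possible unclustered remainder.
#'
#' @param dataset the [expression_dataset()] the result came from.
#' @param de_result a \code{differential_result} from [select_de_genes()].
#' @param floor correlation floor below (or at) which a gene is left
#'   unclustered; default 0.
#' @return The \code{differential_result} with directions filled in.
#' @export
cluster_directions <- function(dataset, de_result, floor = 0) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(de_result, "differential_result"))
  de_idx <- which(de_result$direction != "not_de")
  if (length(de_idx) == 0L) return(de_result)
  sign_dir <- function(md) ifelse(md > 0, "up", ifelse(md < 0, "down", "unclustered"))
  if (length(de_idx) < 2L) {
    de_result$direction[de_idx] <- sign_dir(de_result$mean_diff[de_idx])
    return(de_result)
  }
  prof <- dataset$values[match(de_result$gene[de_idx], dataset$gene_ids), , drop = FALSE]
  sds <- apply(prof, 1, sd)
  flat <- sds == 0
  de_result$direction[de_idx[flat]] <- sign_dir(de_result$mean_diff[de_idx[flat]])
  use <- which(!flat)
  if (length(use) < 2L) {
    de_result$direction[de_idx[use]] <- sign_dir(de_result$mean_diff[de_idx[use]])
    return(de_result)
  }
  z <- t(scale(t(prof[use, , drop = FALSE])))
  md <- de_result$mean_diff[de_idx[use]]
  d <- 1 - cor(t(z))           # correlation distance, n_de x n_de
  med <- c(which.max(md), which.min(md))
  if (med[1] == med[2]) med[2] <- if (med[1] == 1L) 2L else 1L
  assign <- rep(1L, length(use))
  for (it in seq_len(100L)) {
    assign <- ifelse(d[, med[1]] <= d[, med[2]], 1L, 2L)
    new_med <- vapply(1:2, function(k) {
      mem <- which(assign == k)
      if (!length(mem)) return(med[k])
      mem[which.min(colSums(d[mem, mem, drop = FALSE]))]
    }, integer(1))
    if (identical(new_med, med)) break
    med <- new_med
  }
  ga <- dataset$condition == levels(dataset$condition)[1]
  for (k in 1:2) {
    mem <- which(assign == k)
    if (!length(mem)) next
    centroid <- colMeans(z[mem, , drop = FALSE])
    contrast <- mean(centroid[ga]) - mean(centroid[!ga])
    lab <- if (contrast > 0) "up" else if (contrast < 0) "down" else "up"
    cc <- as.vector(cor(t(z[mem, , drop = FALSE]), centroid))
    dir <- ifelse(cc <= floor, "unclustered", lab)
    de_result$direction[de_idx[use[mem]]] <- dir
  }
  de_result
}
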