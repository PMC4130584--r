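#' Chance-corrected kappa between two term memberships
#'
#' Cohen's kappa between the binary membership vectors of two gene sets over
#' a reference set: with a = |A ∩ B|, b = |A \\ B|, c = |B \\ A|,
#' d = N - a - b - c, observed agreement po = (a + d)/N and chance agreement
#' pe = ((a+b)(a+c) + (c+d)(b+d))/N^2, kappa = (po - pe)/(1 - pe). When both
#' memberships are constant (pe = 1) the convention is 1 for identical
#' memberships, 0 otherwise.
#'
#' @param term_a_genes,term_b_genes gene id vectors, subsets of
#'   \code{reference}.
#' @param reference the reference gene set (N >= 2), conventionally the
#'   layer's DE genes.
#' @return kappa in [-1, 1].
#' @export
kappa_score <- function(term_a_genes, term_b_genes, reference) {
  reference <- unique(reference)
  if (length(reference) < 2L) stop("reference must contain at least 2 genes")
  term_a_genes <- unique(term_a_genes); term_b_genes <- unique(term_b_genes)
  if (!all(term_a_genes %in% reference) || !all(term_b_genes %in% reference))
    stop("term gene sets must be subsets of the reference")
  N <- length(reference)
  a <- length(intersect(term_a_genes, term_b_genes))
  b <- length(setdiff(term_a_genes, term_b_genes))
  c_ <- length(setdiff(term_b_genes, term_a_genes))
  d <- N - a - b - c_
  po <- (a + d) / N
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / N^2
  if (abs(1 - pe) < 1e-12) {
    return(if (b == 0 && c_ == 0) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Build the kappa similarity graph of significant terms
#'
#' One node per significant term; an edge joins two terms iff the kappa of
#' their hit-gene memberships (term ∩ layer DE genes) strictly exceeds
#' \code{threshold}. The reference set is the layer's DE genes.
#'
#' @param enriched an \code{enrichment_result} for one layer.
#' @param reference the layer's DE gene set.
#' @param threshold kappa edge threshold (strict \code{>}); default 0.3.
#' @return A \code{kappa_graph}: list with \code{nodes} (term ids),
#'   \code{members} (named list of hit-gene sets), \code{edges} (data.frame
#'   a, b, kappa), \code{reference_size}.
#' @export
build_kappa_graph <- function(enriched, reference, threshold = 0.3) {
  stopifnot(threshold >= -1, threshold <= 1)
  ids <- enriched$term_id
  members <- setNames(lapply(enriched$hit_genes, function(h)
    strsplit(h, ";", fixed = TRUE)[[1]]), ids)
  edges <- data.frame(a = character(), b = character(), kappa = numeric(),
                      stringsAsFactors = FALSE)
  if (length(ids) >= 2L) {
    pairs <- utils::combn(seq_along(ids), 2)
    kv <- apply(pairs, 2, function(ij)
      kappa_score(members[[ij[1]]], members[[ij[2]]], reference))
    keep <- kv > threshold
    edges <- data.frame(a = ids[pairs[1, keep]], b = ids[pairs[2, keep]],
                        kappa = kv[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = ids, members = members, edges = edges,
                 reference_size = length(unique(reference)),
                 threshold = threshold),
            class = "kappa_graph")
}

#' Merge kappa-linked terms into annotation groups
#'
#' Initial groups are the closed neighborhoods (a term plus its kappa
#' neighbors) of every term with at least one edge; terms without edges form
#' singleton groups. Groups are then merged iteratively: at each step the
#' pair of groups sharing the largest fraction of the smaller group's terms
#' is merged, provided that fraction reaches \code{share_threshold}; ties go
#' to the pair whose combined sorted member list is lexicographically
#' smallest. Iteration reaches a fixed point because each merge reduces the
#' group count by one.
#'
#' @param kgraph a \code{kappa_graph}.
#' @param share_threshold merge threshold on the shared fraction of the
#'   smaller group, in (0, 1]; default 0.5.
#' @return list of character vectors (sorted term ids), one per final group,
#'   ordered by first member id.
#' @export
merge_groups <- function(kgraph, share_threshold = 0.5) {
  stopifnot(share_threshold > 0, share_threshold <= 1)
  ids <- kgraph$nodes
  if (!length(ids)) return(list())
  nb <- setNames(lapply(ids, function(i) i), ids)
  for (r in seq_len(nrow(kgraph$edges))) {
    a <- kgraph$edges$a[r]; b <- kgraph$edges$b[r]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  groups <- unique(lapply(nb, function(g) sort(unique(g))))
  repeat {
    if (length(groups) < 2L) break
    best <- NULL; best_share <- -1; best_key <- NULL
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      shared <- length(intersect(groups[[i]], groups[[j]]))
      share <- shared / min(length(groups[[i]]), length(groups[[j]]))
      if (share < share_threshold) next
      key <- paste(sort(union(groups[[i]], groups[[j]])), collapse = "\r")
      if (share > best_share || (share == best_share && key < best_key)) {
        best <- c(i, j); best_share <- share; best_key <- key
      }
    }
    if (is.null(best)) break
    merged <- sort(union(groups[[best[1]]], groups[[best[2]]]))
    groups <- c(groups[-best], list(merged))
    groups <- unique(groups)
  }
  groups[order(vapply(groups, `[`, character(1), 1))]
}

#' Label annotation groups and assign direction
#'
#' Types each member term as up (\code{pct_up >= pct_up_threshold}), down
#' (\code{pct_up <= 1 - pct_up_threshold}) or mixed; the group label terms
#' are the minimum-adjusted-p up term and/or minimum-adjusted-p down term
#' among the members (the overall minimum-p term if all members are mixed).
#' The group direction is up/down if the pooled (union) hit genes of the
#' group pass the same threshold, mixed otherwise.
#'
#' @param group_terms character vector of member term ids.
#' @param enriched the layer's \code{enrichment_result}.
#' @param directions named character vector gene -> direction.
#' @param pct_up_threshold direction threshold in (0.5, 1]; default 0.6.
#' @return An \code{annotation_group}: list with members, term_directions,
#'   label_terms, direction, leading_p_bonferroni, layer, n_genes.
#' @export
label_and_direct <- function(group_terms, enriched, directions,
                             pct_up_threshold = 0.6) {
  stopifnot(pct_up_threshold > 0.5, pct_up_threshold <= 1)
  idx <- match(group_terms, enriched$term_id)
  if (anyNA(idx)) stop("group terms absent from enrichment result")
  sub <- enriched[idx, , drop = FALSE]
  type_of <- function(p_up) {
    if (is.nan(p_up)) return("mixed")
    if (p_up >= pct_up_threshold) "up"
    else if (p_up <= 1 - pct_up_threshold) "down"
    else "mixed"
  }
  term_dir <- vapply(sub$pct_up, type_of, character(1))
  label_terms <- character()
  for (dd in c("up", "down")) {
    cand <- which(term_dir == dd)
    if (length(cand)) {
      cand <- cand[order(sub$p_bonferroni[cand], sub$term_id[cand])]
      label_terms <- c(label_terms, sub$term_id[cand[1]])
    }
  }
  if (!length(label_terms)) {
    o <- order(sub$p_bonferroni, sub$term_id)
    label_terms <- sub$term_id[o[1]]
  }
  pooled <- unique(unlist(strsplit(sub$hit_genes, ";", fixed = TRUE)))
  pool_up <- mean(directions[pooled] == "up")
  structure(list(members = sort(group_terms),
                 term_directions = setNames(term_dir, sub$term_id),
                 label_terms = label_terms,
                 direction = type_of(pool_up),
                 leading_p_bonferroni = min(sub$p_bonferroni),
                 layer = sub$layer[1],
                 n_genes = length(pooled)),
            class = "annotation_group")
}

#' @export
print.annotation_group <- function(x, ...) {
  cat(sprintf("annotation_group [%s, %s]: %d terms, %d genes, leading p = %.3g\n",
              x$layer, x$direction, length(x$members), x$n_genes,
              x$leading_p_bonferroni))
  cat("  label:", paste(x$label_terms, collapse = ", "), "\n")
  invisible(x)
}
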