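# Neighbor-joining trees, the Mantel permutation test and a cophenetic
# tree-agreement score. NJ and cophenetic distances delegate to ape, the
# package the rest of this field builds on.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]. Negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to zero with
#' the difference transferred to the adjacent branches so path lengths
#' through the node are preserved where possible.
#'
#' @param dm symmetric labelled distance matrix (>= 3 labels, no NA).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- unclass(dm)
  if (nrow(dm) < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (anyNA(dm[upper.tri(dm)]))
    stop("distance matrix contains undefined entries", call. = FALSE)
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    l <- tr$edge.length[e]
    node <- tr$edge[e, 2L]
    tr$edge.length[e] <- 0
    below <- which(tr$edge[, 1L] == node)
    if (length(below)) tr$edge.length[below] <- tr$edge.length[below] + l
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

upper_vec <- function(m) m[upper.tri(m)]

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the vectorized upper
#' triangles. The permutation null jointly permutes rows and columns of
#' the second matrix; the one-sided p-value is
#' `(1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param dm1,dm2 symmetric labelled distance matrices over the same
#'   label set (order may differ; `dm2` is aligned to `dm1`).
#' @param n_perm number of random permutations. Default 999.
#' @param seed optional integer seed for reproducibility.
#' @param permutations optional integer matrix (one permutation of
#'   `1:n` per row) used instead of random draws, e.g. for exhaustive
#'   enumeration on small matrices.
#' @return object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `seed`.
#' @export
mantel_test <- function(dm1, dm2, n_perm = 999L, seed = NULL,
                        permutations = NULL) {
  dm1 <- unclass(dm1); dm2 <- unclass(dm2)
  if (!setequal(rownames(dm1), rownames(dm2)))
    stop("matrices have different label sets", call. = FALSE)
  dm2 <- dm2[rownames(dm1), rownames(dm1)]
  v1 <- upper_vec(dm1)
  if (sd(v1) == 0 || sd(upper_vec(dm2)) == 0)
    stop("constant matrix: Mantel r undefined", call. = FALSE)
  r_obs <- cor(v1, upper_vec(dm2))
  n <- nrow(dm1)
  if (is.null(permutations)) {
    if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    permutations <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n)))
  }
  r_perm <- apply(permutations, 1L, function(p)
    cor(v1, upper_vec(dm2[p, p])))
  p_val <- (1 + sum(r_perm >= r_obs)) / (nrow(permutations) + 1)
  structure(list(r = r_obs, p = p_val, n_perm = nrow(permutations),
                 seed = seed), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test: r =", round(x$r, 4), ", p =", signif(x$p, 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Cophenetic agreement between two trees
#'
#' Pearson correlation between the cophenetic (patristic path-length)
#' distance matrices of two trees over the same leaves. 1 means identical
#' distance structure.
#'
#' @param t1,t2 `ape::phylo` trees with identical leaf sets.
#' @return correlation in `[-1, 1]`.
#' @export
tree_agreement <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  c1 <- ape::cophenetic.phylo(t1)
  c2 <- ape::cophenetic.phylo(t2)[rownames(c1), colnames(c1)]
  cor(upper_vec(c1), upper_vec(c2))
}
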