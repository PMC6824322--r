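#' Hamming distance matrix between haplotype strings
#'
#' @param strings Character vector of equal-length allele strings.
#' @param labels Row/column labels (default the strings' names or
#'   `Hap1..Hapk`).
#' @return Symmetric integer matrix of pairwise mismatch counts with zero
#'   diagonal.
#' @export
hamming_distance_matrix <- function(strings, labels = NULL) {
  k <- length(strings)
  if (k < 1) stop_invalid("`strings` must not be empty.")
  if (length(unique(nchar(strings))) != 1L) {
    stop_invalid("All strings must have equal length.")
  }
  labels <- labels %||% names(strings) %||% paste0("Hap", seq_len(k))
  mat <- do.call(rbind, strsplit(strings, ""))
  D <- matrix(0L, k, k, dimnames = list(labels, labels))
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        D[i, j] <- D[j, i] <- sum(mat[i, ] != mat[j, ])
      }
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` is joined (ties broken by the
#' smallest pair of label indices), branch lengths follow the standard NJ
#' equations (negative lengths are clamped to zero and flagged), and reduced
#' distances are `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`.  The method
#' reconstructs the generating tree exactly when the input distances are
#' additive.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal
#'   (at least 2 taxa).
#' @param labels Taxon labels (default `rownames(D)`).
#' @return Object of class `nj_tree`: list with `newick` (unrooted tree
#'   string), `n_taxa`, and `negative_branches` (count clamped to 0).
#' @export
neighbor_joining <- function(D, labels = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop_invalid("Neighbor joining needs at least 2 taxa.")
  if (!isSymmetric(unname(D), tol = 1e-8) || any(D < 0) ||
      any(abs(diag(D)) > 1e-12)) {
    stop_invalid("`D` must be symmetric, non-negative, with zero diagonal.")
  }
  labels <- labels %||% rownames(D) %||% paste0("t", seq_len(n))
  nodes <- as.list(labels)        # newick fragment per active node
  order_idx <- seq_len(n)         # original label index, for tie-breaks
  clamped <- 0L
  fmt <- function(x) formatC(x, format = "g", digits = 15)

  while (length(nodes) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    # candidate pairs within numerical tolerance of the minimum
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- order(pmin(order_idx[cand[, 1]], order_idx[cand[, 2]]),
                 pmax(order_idx[cand[, 1]], order_idx[cand[, 2]]))
    i <- cand[key[1], 1]; j <- cand[key[1], 2]

    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; lj <- 0 }
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(li),
                        nodes[[j]], fmt(lj))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_node)
    order_idx <- c(order_idx[keep], min(order_idx[c(i, j)]))
  }

  if (length(nodes) == 2L) {
    d <- D[1, 2]
    newick <- sprintf("(%s:%s,%s:%s);", nodes[[1]], fmt(d / 2),
                      nodes[[2]], fmt(d / 2))
  } else {
    l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    for (v in c("l1", "l2", "l3")) {
      if (get(v) < 0) { clamped <- clamped + 1L; assign(v, 0) }
    }
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                      nodes[[1]], fmt(l1), nodes[[2]], fmt(l2),
                      nodes[[3]], fmt(l3))
  }
  structure(list(newick = newick, n_taxa = n, negative_branches = clamped),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat(sprintf("<nj_tree> %d taxa%s\n%s\n", x$n_taxa,
              if (x$negative_branches)
                sprintf(" (%d negative branch(es) clamped)", x$negative_branches)
              else "",
              x$newick))
  invisible(x)
}

#' Convert an `nj_tree` to an ape `phylo` object
#'
#' @param x An [neighbor_joining()] result.
#' @return An `ape::phylo` tree.
#' @export
as_phylo <- function(x) {
  stopifnot(inherits(x, "nj_tree"))
  ape::read.tree(text = x$newick)
}
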