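## Pairwise genetic distances, UPGMA dendrograms with Newick export, and
## PCA of the dosage matrix.

#' Pairwise genetic distance matrix
#'
#' Default metric is simple mismatch, 1 - concordance over jointly called
#' loci, which is encoding-agnostic across mixed ploidies. The
#' alternative is Euclidean distance on scale-normalised calls
#' (call / encoding scale, equivalently dosage / ploidy), root-mean-
#' squared over jointly called loci.
#'
#' @param m A `genotype_matrix`.
#' @param metric `"mismatch"` (default) or `"euclidean"`.
#' @param min_overlap Pairs with fewer jointly called loci get `NA`.
#' @return Object of class `"dist_matrix"`: symmetric numeric matrix with
#'   zero diagonal and accession-id dimnames; attribute `"metric"`
#'   records the choice.
#' @export
pairwise_distance <- function(m, metric = c("mismatch", "euclidean"),
                              min_overlap = 1L) {
  metric <- match.arg(metric)
  scale <- encoding_scale(m$encoding)
  if (metric == "mismatch") {
    cm <- concordance_matrix(m)
    d <- 1 - cm$concordance
    d[cm$overlap < min_overlap] <- NA_real_
  } else {
    x <- m$calls / scale
    called <- !is.na(x)
    storage.mode(called) <- "double"
    x0 <- x
    x0[is.na(x0)] <- 0
    overlap <- tcrossprod(called)
    # sum over joint loci of (xi - xj)^2, via the usual cross-product split
    sq <- tcrossprod(x0^2, called)
    ss <- sq + t(sq) - 2 * tcrossprod(x0)
    d <- sqrt(pmax(ss, 0) / pmax(overlap, 1))
    d[overlap < min_overlap] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m$calls), rownames(m$calls))
  structure(d, metric = metric, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d accessions, metric '%s'\n", nrow(x),
              attr(x, "metric")))
  invisible(x)
}

#' UPGMA hierarchical clustering
#'
#' Size-weighted average-linkage agglomeration. Merge heights record the
#' joining distance; node heights on the tree are half of it, so
#' cophenetic distances reconstruct joining distances and every
#' root-to-leaf path has equal length (the tree is ultrametric). Ties in
#' the minimal distance are broken by merging the pair whose smallest
#' member ids sort lexicographically first, for reproducibility.
#'
#' @param d Complete symmetric distance matrix with dimnames (a
#'   `dist_matrix` or plain matrix); missing entries are an error
#'   (impute or raise `min_overlap` coverage first).
#' @return Object of class `"upgma_tree"`: `merge` (hclust convention),
#'   `height` (joining distances), `labels`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d)))
    stop("distance matrix has missing entries; impute before clustering")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("need at least two accessions to cluster")
  labels <- rownames(d)
  active <- seq_len(n)                    # current cluster rows of d
  node_of <- -seq_len(n)                  # hclust code of each cluster
  min_id <- labels                        # smallest leaf label per cluster
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  work <- d
  for (step in seq_len(n - 1L)) {
    na <- length(active)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(na - 1L)) {
      for (j in seq.int(i + 1L, na)) {
        dij <- work[active[i], active[j]]
        if (dij < best_d - 1e-15) {
          best_d <- dij
          best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-15) {
          key_new <- sort(c(min_id[active[i]], min_id[active[j]]))
          key_old <- sort(c(min_id[active[best[1]]], min_id[active[best[2]]]))
          if (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    a <- active[best[1]]; b <- active[best[2]]
    merge[step, ] <- sort(c(node_of[a], node_of[b]))
    height[step] <- work[a, b]
    # size-weighted average linkage update, result kept in slot a
    for (other in setdiff(active, c(a, b))) {
      nd <- (size[a] * work[a, other] + size[b] * work[b, other]) /
        (size[a] + size[b])
      work[a, other] <- work[other, a] <- nd
    }
    size[a] <- size[a] + size[b]
    node_of[a] <- step
    min_id[a] <- min(min_id[a], min_id[b])
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("upgma_tree: %d leaves, root joining distance %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

node_leafsets <- function(t) {
  n <- length(t$labels)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    grab <- function(code) if (code < 0L) -code else sets[[code]]
    sets[[s]] <- c(grab(t$merge[s, 1]), grab(t$merge[s, 2]))
  }
  sets
}

#' Cophenetic distances of a UPGMA tree
#'
#' For two leaves, the joining distance at their lowest common ancestor
#' (twice the node height).
#'
#' @param t An `upgma_tree`.
#' @return Symmetric matrix in input-label order.
#' @export
cophenetic_matrix <- function(t) {
  n <- length(t$labels)
  out <- matrix(0, n, n, dimnames = list(t$labels, t$labels))
  sets <- node_leafsets(t)
  for (s in seq_len(n - 1L)) {
    left <- if (t$merge[s, 1] < 0L) -t$merge[s, 1] else sets[[t$merge[s, 1]]]
    right <- if (t$merge[s, 2] < 0L) -t$merge[s, 2] else sets[[t$merge[s, 2]]]
    out[left, right] <- t$height[s]
    out[right, left] <- t$height[s]
  }
  out
}

#' Convert a UPGMA tree to hclust
#'
#' @param t An `upgma_tree`.
#' @return A `stats::hclust` object (heights are joining distances).
#' @export
as_hclust <- function(t) {
  ord <- integer(0)
  walk <- function(code) {
    if (code < 0L) {
      ord <<- c(ord, -code)
    } else {
      walk(t$merge[code, 1])
      walk(t$merge[code, 2])
    }
  }
  walk(length(t$height))
  structure(list(merge = t$merge, height = t$height, order = ord,
                 labels = t$labels, method = "upgma (size-weighted)",
                 call = match.call(), dist.method = "precomputed"),
            class = "hclust")
}

#' Serialise a UPGMA tree as Newick text
#'
#' Branch lengths derive from node heights of half the joining distance,
#' so the tree is ultrametric in the written lengths. Child ordering is
#' canonical (subtree containing the smallest leaf id first): permuting
#' the input leaf order yields identical text.
#'
#' @param t An `upgma_tree`.
#' @param digits Significant digits for branch lengths.
#' @return Newick string, semicolon-terminated.
#' @export
to_newick <- function(t, digits = 10L) {
  fmt <- function(x) format(x, digits = digits, trim = TRUE,
                            scientific = FALSE)
  sets <- node_leafsets(t)
  render <- function(code, parent_h) {
    if (code < 0L) {
      leaf <- -code
      return(list(text = sprintf("%s:%s", t$labels[leaf], fmt(parent_h)),
                  min_id = t$labels[leaf]))
    }
    h <- t$height[code] / 2
    kids <- lapply(t$merge[code, ], render, parent_h = h)
    kids <- kids[order(vapply(kids, `[[`, "", "min_id"))]
    inner <- paste(vapply(kids, `[[`, "", "text"), collapse = ",")
    txt <- sprintf("(%s)", inner)
    if (is.finite(parent_h)) txt <- sprintf("%s:%s", txt, fmt(parent_h - h))
    list(text = txt, min_id = min(vapply(kids, `[[`, "", "min_id")))
  }
  root <- render(length(t$height), Inf)
  paste0(root$text, ";")
}

#' Write a tree to a Newick file
#'
#' @param t An `upgma_tree`.
#' @param path Output path.
#' @param digits Significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path, digits = 10L) {
  writeLines(to_newick(t, digits), path)
  invisible(path)
}

#' Principal component analysis of the dosage matrix
#'
#' Calls are scale-normalised (call / encoding scale), missing values are
#' mean-imputed per marker, columns are centred, and the decomposition is
#' delegated to [stats::prcomp()].
#'
#' @param m A `genotype_matrix`.
#' @param n_components Number of components to return.
#' @return List of class `"dosage_pca"`: `scores` (accessions x
#'   components), `var_pct` (percent variance per component, computed
#'   against the total variance of the imputed matrix), `rotation`.
#' @export
pca_dosage <- function(m, n_components = 10L) {
  scale <- encoding_scale(m$encoding)
  x <- m$calls / scale
  n_components <- min(n_components, nrow(x))
  if (ncol(x) < n_components)
    stop("fewer markers than requested components")
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    x[is.na(x[, j]), j] <- mu
  }
  x <- sweep(x, 2L, colMeans(x))
  pc <- stats::prcomp(x, center = FALSE)
  total_var <- sum(pc$sdev^2)
  keep <- seq_len(min(n_components, ncol(pc$x)))
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 var_pct = 100 * pc$sdev[keep]^2 / total_var,
                 rotation = pc$rotation[, keep, drop = FALSE]),
            class = "dosage_pca")
}

#' @export
print.dosage_pca <- function(x, ...) {
  cat("dosage_pca:", paste(sprintf("PC%d %.2f%%", seq_along(x$var_pct),
                                   x$var_pct), collapse = ", "), "\n")
  invisible(x)
}
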