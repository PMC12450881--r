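# Band-sharing distances, UPGMA clustering and marker PCA.

#' Pairwise accession distances from band presence data
#'
#' Dice (Nei & Li) distance `1 - 2a/(2a + b + c)` over band-slot presence
#' counts (`a` shared 1s, `b`/`c` one-sided 1s), or simple matching
#' distance `(b + c) / slots`. Slots that are `NA` in either accession are
#' excluded pairwise (band matrices built by this package contain no `NA`;
#' the guard covers externally supplied scores).
#'
#' @param bands a [band_matrix()].
#' @param method `"dice"` (default, the standard choice for fingerprint
#'   band data) or `"simple_matching"`.
#' @return a [distance_matrix()] over accessions.
#' @export
accession_distance <- function(bands, method = c("dice", "simple_matching")) {
  stopifnot(inherits(bands, "band_matrix"))
  method <- match.arg(method)
  b <- bands$bands
  n <- nrow(b)
  if (n < 2L) stop("accession_distance: need at least 2 accessions")
  d <- matrix(0, n, n, dimnames = list(rownames(b), rownames(b)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(b[i, ]) & !is.na(b[j, ])
    if (!any(ok))
      stop("accession_distance: no comparable band slots between '",
           rownames(b)[i], "' and '", rownames(b)[j], "'")
    x <- b[i, ok]; y <- b[j, ok]
    if (method == "dice") {
      a <- sum(x == 1 & y == 1)
      bc <- sum(x != y)
      d[i, j] <- d[j, i] <- if (2 * a + bc == 0) 0 else 1 - 2 * a / (2 * a + bc)
    } else {
      d[i, j] <- d[j, i] <- sum(x != y) / sum(ok)
    }
  }
  distance_matrix(d)
}

#' UPGMA clustering of a distance matrix
#'
#' Agglomerative clustering with arithmetic-mean (average) linkage: the
#' closest pair of clusters is merged at height `d/2` (so the patristic
#' distance between two leaves of an ultrametric input equals their
#' original distance) and the new cluster's distance to every other
#' cluster is the size-weighted mean of its members' distances. Exact
#' distance ties are broken lexicographically by each cluster's smallest
#' leaf label, making the tree reproducible.
#'
#' @param dist a [distance_matrix()] over at least two leaves.
#' @return an object of class `upgma_tree`: `merge` ((n-1) x 2, `hclust`
#'   convention), `height` (merge heights, `d/2` scale), `labels`.
#' @export
upgma <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  d <- unclass(dist)
  if (anyNA(d)) stop("upgma: distance matrix contains NA")
  n <- nrow(d)
  if (n < 2L) stop("upgma: need at least 2 leaves")
  labels <- rownames(d)
  # active cluster bookkeeping
  id <- -seq_len(n)                 # hclust convention: negative = leaf
  size <- rep(1L, n)
  rep_lab <- labels                 # lexicographically smallest member label
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  D <- d
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ii in seq_along(idx)[-length(idx)]) for (jj in (ii + 1L):length(idx)) {
      i <- idx[ii]; j <- idx[jj]
      dij <- D[i, j]
      key <- sort(c(rep_lab[i], rep_lab[j]))
      if (dij < best_d ||
          (dij == best_d && (key[1L] < best_key[1L] ||
                             (key[1L] == best_key[1L] && key[2L] < best_key[2L])))) {
        best_d <- dij; best <- c(i, j); best_key <- key
      }
    }
    i <- best[1L]; j <- best[2L]
    if (rep_lab[j] < rep_lab[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(id[i], id[j])   # lex-smaller representative first
    height[step] <- best_d / 2
    # weighted-average update into slot i
    for (k in idx) if (k != i && k != j)
      D[i, k] <- D[k, i] <- (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    id[i] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = "upgma"),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("upgma_tree:", length(x$labels), "leaves, root height",
      format(max(x$height)), "\n")
  invisible(x)
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  # hclust heights are on the distance scale (2 x merge height)
  structure(list(merge = x$merge, height = 2 * x$height,
                 order = tree_leaf_order(x), labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "band"),
            class = "hclust")
}

tree_leaf_order <- function(tree) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(tree$merge[node, 1L]), rec(tree$merge[node, 2L]))
  }
  rec(nrow(tree$merge))
}

#' Serialize a tree to Newick
#'
#' Branch lengths are differences of merge heights, printed with enough
#' digits that re-parsing reproduces the tree to 6 decimals. A degenerate
#' single-leaf tree serializes as `"label;"`.
#'
#' @param tree an `upgma_tree` (or a list with `merge`, `height`,
#'   `labels` in `hclust` convention and heights on the merge-height
#'   scale).
#' @param digits decimal places for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 6) {
  labels <- tree$labels
  if (is.null(labels) || anyNA(labels) || any(labels == ""))
    stop("write_newick: every leaf must be labelled")
  if (length(labels) == 1L) return(paste0(labels, ";"))
  fmt <- function(x) {
    s <- sprintf(paste0("%.", digits, "f"), x)
    s <- sub("0+$", "", s)
    sub("\\.$", "", s)
  }
  node_str <- function(node, parent_h) {
    if (node < 0L)
      return(paste0(labels[-node], ":", fmt(parent_h)))
    h <- tree$height[node]
    kids <- vapply(tree$merge[node, ], node_str, "", parent_h = h)
    paste0("(", paste(kids, collapse = ","), "):", fmt(parent_h - h))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  kids <- vapply(tree$merge[root, ], node_str, "", parent_h = h)
  paste0("(", paste(kids, collapse = ","), ");")
}

#' Convert a UPGMA tree to an ape phylo object
#' @param tree an `upgma_tree`.
#' @return an [ape::read.tree()] `phylo` object (for plotting etc.).
#' @export
as_phylo <- function(tree) ape::read.tree(text = write_newick(tree, digits = 10))

#' Cut a UPGMA tree into k groups
#'
#' Removes the `k - 1` highest merges and labels the resulting groups
#' 1..k in order of first appearance along the leaf label order.
#'
#' @param tree an `upgma_tree`.
#' @param k number of groups, `1 <= k <=` number of leaves.
#' @return named integer vector of group labels per leaf.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("cut_tree: k must be in [1, ", n, "]")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_leaf <- integer(nrow(tree$merge))  # one leaf per merged cluster
  keep <- order(tree$height)[seq_len(n - k)]
  for (m in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[m, ]
    leaves <- ifelse(kids < 0L, -kids, node_leaf[pmax(kids, 1L)])
    node_leaf[m] <- leaves[1L]
    if (m %in% keep) {
      a <- find(leaves[1L]); b <- find(leaves[2L])
      parent[b] <- a
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  groups <- match(root, unique(root))
  stats::setNames(groups, tree$labels)
}

#' PCA of marker band data
#'
#' Column-centres the binary band matrix and eigendecomposes its
#' covariance, returning accession coordinates and explained-variance
#' proportions for the leading components.
#'
#' @param bands a [band_matrix()].
#' @param n_components number of components to return.
#' @return list with `coordinates` (accession x component), `proportions`
#'   (fraction of total variance per returned component), `sdev`.
#' @export
marker_pca <- function(bands, n_components = 3L) {
  stopifnot(inherits(bands, "band_matrix"))
  b <- bands$bands
  if (nrow(b) < 2L) stop("marker_pca: need at least 2 accessions")
  pc <- stats::prcomp(b, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) stop("marker_pca: constant band matrix, variance undefined")
  n_components <- min(n_components, length(pc$sdev))
  list(coordinates = pc$x[, seq_len(n_components), drop = FALSE],
       proportions = (pc$sdev^2 / tot)[seq_len(n_components)],
       sdev = pc$sdev)
}
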