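# Independent oracles used across the suite. These stay deliberately
# naive (explicit loops, exhaustive enumeration) so they check the
# package's vectorised/greedy implementations from a different route.

# PIC by explicit double loop over allele pairs
pic_bruteforce <- function(p) {
  out <- 1 - sum(p^2)
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j) out <- out - 2 * p[i]^2 * p[j]^2
  }
  out
}

# random frequency vector of k alleles (normalized gamma draws)
random_freqs <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# random symmetric distance matrix with distinct off-diagonal entries
random_distance <- function(n, labels = LETTERS[seq_len(n)]) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- stats::runif(n * (n - 1) / 2, 0.1, 2)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  distance_matrix(m)
}

# cophenetic (tree-implied) distances from an upgma_tree, on the
# original distance scale (2 x merge height of the joining node)
tree_cophenetic <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", nrow(tree$merge))
  d <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (m in seq_len(nrow(tree$merge))) {
    kids <- lapply(tree$merge[m, ], function(k)
      if (k < 0L) -k else members[[k]])
    for (a in kids[[1L]]) for (b in kids[[2L]])
      d[a, b] <- d[b, a] <- 2 * tree$height[m]
    members[[m]] <- c(kids[[1L]], kids[[2L]])
  }
  d
}

# exhaustive minimum discriminating primer-set size
exhaustive_min_primers <- function(bands) {
  b <- bands$bands
  np <- length(bands$primer_names)
  pattern <- vapply(seq_len(np), function(j)
    paste0(b[, 2L * j - 1L], b[, 2L * j]), character(nrow(b)))
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = nrow(b))
  full <- length(unique(apply(pattern, 1L, paste, collapse = "")))
  for (size in 0:np) {
    for (subset in combn_list(np, size)) {
      codes <- if (length(subset))
        apply(pattern[, subset, drop = FALSE], 1L, paste, collapse = "")
      else rep("", nrow(b))
      if (length(unique(codes)) == full) return(size)
    }
  }
  np
}

combn_list <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  asplit(utils::combn(n, k), 2L)
}

# cluster agreement after best label permutation (small K)
max_label_agreement <- function(est, truth) {
  ks <- sort(unique(truth))
  perms <- perm_all(length(ks))
  best <- 0
  for (pm in perms) {
    mapped <- ks[pm][match(est, sort(unique(est)))]
    best <- max(best, mean(mapped == truth))
  }
  best
}

perm_all <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (pm in perm_all(k - 1L)) for (pos in seq_len(k))
    out[[length(out) + 1L]] <- append(pm, k, after = pos - 1L)
  out
}
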