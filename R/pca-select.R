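# PCA-based comprehensive scoring and representative-accession selection.

#' Principal component analysis of standardized traits
#'
#' Mean-imputes missing cells, z-score standardizes each trait and
#' eigendecomposes the correlation matrix. By default only quantitative
#' traits enter; coded qualitative traits can be included with
#' `include_qualitative = TRUE`. Components with eigenvalue > 1 (Kaiser
#' rule) are marked retained.
#'
#' @param traits a [trait_matrix()].
#' @param standardize if `FALSE`, traits are centred but not scaled
#'   (covariance PCA).
#' @param include_qualitative include qualitative class codes as numeric
#'   columns.
#' @param retain `"kaiser"` (eigenvalue > 1) or an integer count.
#' @return object of class `pheno_pca`: `loadings` (trait x component
#'   eigenvectors), `eigenvalues`, `proportions` (explained-variance
#'   fractions summing to 1), `scores` (accession x component),
#'   `retained` (component indices).
#' @export
pheno_pca <- function(traits, standardize = TRUE, include_qualitative = FALSE,
                      retain = "kaiser") {
  stopifnot(inherits(traits, "trait_matrix"))
  keep <- if (include_qualitative) rep(TRUE, ncol(traits$values))
          else traits$kinds == "quantitative"
  v <- traits$values[, keep, drop = FALSE]
  if (ncol(v) < 2L) stop("pheno_pca: need at least 2 trait columns")
  if (any(colSums(!is.na(v)) == 0L)) stop("pheno_pca: all-missing trait column")
  for (j in seq_len(ncol(v))) {
    na <- is.na(v[, j])
    if (any(na)) v[na, j] <- mean(v[, j], na.rm = TRUE)
  }
  if (nrow(v) < ncol(v))
    warning("pheno_pca: fewer accessions than traits; components beyond n-1 are degenerate")
  z <- scale(v, center = TRUE, scale = standardize)
  cmat <- stats::cov(z)
  eg <- eigen(cmat, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  loadings <- eg$vectors
  # fix the eigenvector sign ambiguity: largest-magnitude loading positive
  for (j in seq_len(ncol(loadings))) {
    pivot <- which.max(abs(loadings[, j]))
    if (loadings[pivot, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(v), paste0("PC", seq_len(ncol(v))))
  scores <- z %*% loadings
  retained_idx <- if (identical(retain, "kaiser")) which(ev > 1)
                  else seq_len(min(as.integer(retain), length(ev)))
  if (!length(retained_idx)) retained_idx <- 1L
  structure(list(loadings = loadings, eigenvalues = ev,
                 proportions = ev / sum(ev), scores = scores,
                 retained = retained_idx, standardized = standardize),
            class = "pheno_pca")
}

#' @export
print.pheno_pca <- function(x, ...) {
  k <- min(length(x$eigenvalues), max(x$retained, 4L))
  cat("pheno_pca:", nrow(x$scores), "accessions,", ncol(x$scores), "components\n")
  cat("explained (%):",
      paste0(formatC(100 * x$proportions[1:k], digits = 2, format = "f"),
             collapse = ", "), "...\n")
  cat("retained (eigenvalue > 1):", length(x$retained), "\n")
  invisible(x)
}

#' Comprehensive F score per accession
#'
#' Variance-weighted sum of the retained component scores:
#' `F = sum_i w_i * score_i` with `w_i` the component's explained-variance
#' proportion renormalized over the components used. Higher F indicates a
#' better overall phenotype, so F ranks accessions for selection.
#'
#' @param pca a [pheno_pca()] fit.
#' @param n_components how many leading components to combine (default:
#'   the retained set).
#' @return named numeric vector of F scores (one per accession).
#' @export
comprehensive_score <- function(pca, n_components = NULL) {
  stopifnot(inherits(pca, "pheno_pca"))
  if (is.null(n_components)) n_components <- length(pca$retained)
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("comprehensive_score: need at least 1 component")
  if (n_components > ncol(pca$scores))
    stop("comprehensive_score: only ", ncol(pca$scores), " components available")
  idx <- seq_len(n_components)
  w <- pca$proportions[idx] / sum(pca$proportions[idx])
  drop(pca$scores[, idx, drop = FALSE] %*% w)
}

#' Hierarchical clustering of accessions on standardized traits
#'
#' Ward linkage (`ward.D2`) on Euclidean distances over mean-imputed,
#' z-score standardized quantitative traits, cut at `k` clusters.
#' Deterministic for a given input order.
#'
#' @param traits a [trait_matrix()].
#' @param k number of clusters (>= 2, <= accessions).
#' @param include_qualitative include coded qualitative traits.
#' @return named integer vector of cluster labels.
#' @export
cluster_phenotypes <- function(traits, k, include_qualitative = FALSE) {
  stopifnot(inherits(traits, "trait_matrix"))
  n <- nrow(traits$values)
  if (k < 2L) stop("cluster_phenotypes: k must be >= 2")
  if (k > n) stop("cluster_phenotypes: k exceeds the number of accessions")
  keep <- if (include_qualitative) rep(TRUE, ncol(traits$values))
          else traits$kinds == "quantitative"
  v <- traits$values[, keep, drop = FALSE]
  for (j in seq_len(ncol(v))) {
    na <- is.na(v[, j])
    if (any(na)) v[na, j] <- mean(v[, j], na.rm = TRUE)
  }
  z <- scale(v)
  z[, apply(v, 2, stats::sd) == 0] <- 0
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Select representative accessions by cluster quota and F rank
#'
#' Per-cluster quotas are proportional to cluster size (largest-remainder
#' rounding, minimum 1). Within each cluster accessions are taken in
#' descending comprehensive F score. A repair pass then guarantees that
#' every qualitative trait class present in the full collection is
#' carried by at least one selected accession: the highest-F carrier of
#' a missing class is swapped in for the lowest-F selected accession
#' whose removal does not itself break coverage.
#'
#' @param labels cluster labels (named by accession, as from
#'   [cluster_phenotypes()]).
#' @param f comprehensive F scores (named by accession).
#' @param traits a [trait_matrix()] (qualitative columns drive coverage).
#' @param target_n number of accessions to select.
#' @return object of class `selection_result`: `selected` (ids),
#'   `quotas`, `labels`, `f`.
#' @export
select_representatives <- function(labels, f, traits, target_n) {
  stopifnot(inherits(traits, "trait_matrix"))
  ids <- accessions(traits)
  if (is.null(names(labels))) names(labels) <- ids
  if (is.null(names(f))) names(f) <- ids
  stopifnot(setequal(names(labels), ids), setequal(names(f), ids))
  k <- length(unique(labels))
  if (target_n < k)
    stop("select_representatives: target_n (", target_n,
         ") is smaller than the number of clusters (", k, ")")
  if (target_n > length(ids))
    stop("select_representatives: target_n exceeds the number of accessions")
  sizes <- table(labels)
  quota <- largest_remainder(as.numeric(sizes) / length(ids) * target_n,
                             target_n, min_each = 1L,
                             cap = as.integer(sizes))
  names(quota) <- names(sizes)
  selected <- character(0)
  for (cl in names(sizes)) {
    members <- ids[labels[ids] == cl]
    ord <- members[order(-f[members], members)]
    selected <- c(selected, ord[seq_len(quota[cl])])
  }
  # coverage repair over qualitative classes
  qual <- traits$values[, traits$kinds == "qualitative", drop = FALSE]
  covered <- function(sel) {
    miss <- list()
    for (tr in colnames(qual)) {
      all_cls <- unique(stats::na.omit(qual[, tr]))
      sel_cls <- unique(stats::na.omit(qual[sel, tr]))
      gap <- setdiff(all_cls, sel_cls)
      if (length(gap)) miss[[tr]] <- gap
    }
    miss
  }
  repeat {
    miss <- covered(selected)
    if (!length(miss)) break
    tr <- names(miss)[1L]; cls <- miss[[tr]][1L]
    carriers <- ids[!is.na(qual[, tr]) & qual[, tr] == cls & !ids %in% selected]
    if (!length(carriers)) break  # class only on missing rows; nothing to do
    incoming <- carriers[order(-f[carriers], carriers)][1L]
    # drop the lowest-F selected accession whose removal keeps coverage
    by_f <- selected[order(f[selected], selected)]
    out <- NULL
    for (cand in by_f) {
      trial <- c(setdiff(selected, cand), incoming)
      if (!length(covered(trial))) { out <- cand; break }
      # removal may not break classes the incoming one doesn't fix; accept
      # the first candidate that at least does not lose previously covered
      # classes other than via this swap
      miss_trial <- covered(trial)
      if (length(miss_trial) < length(miss) ||
          (length(miss_trial) == length(miss) && !cls %in% unlist(miss_trial))) {
        out <- cand; break
      }
    }
    if (is.null(out)) out <- by_f[1L]
    selected <- c(setdiff(selected, out), incoming)
  }
  structure(list(selected = sort(selected), quotas = quota,
                 labels = labels, f = f, target_n = target_n),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$selected), "of", length(x$labels),
      "accessions selected\n")
  cat("cluster quotas:", paste(names(x$quotas), x$quotas, sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

# largest-remainder apportionment with a per-cell minimum and cap
largest_remainder <- function(shares, total, min_each = 0L, cap = NULL) {
  base <- pmax(floor(shares), min_each)
  if (!is.null(cap)) base <- pmin(base, cap)
  rem <- total - sum(base)
  frac <- shares - floor(shares)
  ord <- order(-frac, seq_along(shares))
  i <- 1L
  while (rem > 0L) {
    j <- ord[(i - 1L) %% length(ord) + 1L]
    if (is.null(cap) || base[j] < cap[j]) { base[j] <- base[j] + 1L; rem <- rem - 1L }
    i <- i + 1L
  }
  while (rem < 0L) {
    # shrink the largest overshoot first, never below the minimum
    j <- which.max(base - shares)
    if (base[j] > min_each) { base[j] <- base[j] - 1L; rem <- rem + 1L }
    else stop("largest_remainder: infeasible quota")
  }
  as.integer(base)
}
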