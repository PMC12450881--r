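# Model-based population structure: the admixture likelihood maximised
# by EM, replicate scans over K, and Evanno delta-K model selection.

#' Convert genotype calls to allele-A dosage
#' @param genotypes a [genotype_matrix()].
#' @return integer matrix with entries 0/1/2 (`BB`/`AB`/`AA`) or `NA`.
#' @export
genotype_dosage <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- matrix(NA_real_, nrow(genotypes$calls), ncol(genotypes$calls),
              dimnames = dimnames(genotypes$calls))
  g[genotypes$calls == "BB"] <- 0
  g[genotypes$calls == "AB"] <- 1
  g[genotypes$calls == "AA"] <- 2
  g
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood point estimation of the admixture model: each
#' individual `i` carries ancestry fractions `q_ik` over `K` source
#' populations with allele frequencies `p_kl`, and its allele-A dosage
#' `g_il` at locus `l` is binomial(2, `f_il`) with
#' `f_il = sum_k q_ik p_kl`. The log-likelihood
#' `sum_il g ln f + (2 - g) ln(1 - f)` is maximised by
#' expectation-maximisation from a seeded random start; it is monotone
#' non-decreasing across iterations and each `Q` row sums to 1 after
#' every update. Frequencies are clamped to `[1e-6, 1 - 1e-6]`; missing
#' genotypes contribute nothing to the likelihood.
#'
#' @param genotypes a [genotype_matrix()] (biallelic loci).
#' @param K number of source populations (>= 1, <= accessions).
#' @param seed integer seed for the random start.
#' @param max_iter iteration cap.
#' @param tol stop when the log-likelihood gain falls below this.
#' @return object of class `admixture_fit`: `K`, `Q` (accession x K,
#'   rows sum to 1), `P` (K x locus allele-A frequencies), `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `seed`.
#' @export
em_admixture <- function(genotypes, K, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  G <- genotype_dosage(genotypes)
  if (K < 1L) stop("em_admixture: K must be >= 1")
  if (K > nrow(G)) stop("em_admixture: K exceeds the number of accessions")
  drop_loci <- colSums(!is.na(G)) == 0L
  if (any(drop_loci)) {
    warning("em_admixture: dropping all-missing locus/loci: ",
            paste(colnames(G)[drop_loci], collapse = ", "))
    G <- G[, !drop_loci, drop = FALSE]
  }
  n <- nrow(G); L <- ncol(G)
  eps <- 1e-6
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0           # zero-filled copy; masked terms vanish
  with_seed(seed, {
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
  })
  loglik <- function(FF) {
    FF <- pmin(pmax(FF, eps), 1 - eps)
    sum((G0 * log(FF) + (2 - G0) * log(1 - FF))[obs])
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  two_nonmiss <- 2 * rowSums(obs)
  for (it in seq_len(max_iter)) {
    FF <- Q %*% P
    FF <- pmin(pmax(FF, eps), 1 - eps)
    num_p <- matrix(0, K, L); den_p <- matrix(0, K, L)
    q_new <- matrix(0, n, K)
    for (k in seq_len(K)) {
      A <- (Q[, k] %o% P[k, ]) / FF          # E[A-alleles from k] / g
      B <- (Q[, k] %o% (1 - P[k, ])) / (1 - FF)
      a_term <- G0 * A; b_term <- (2 - G0) * B
      a_term[!obs] <- 0; b_term[!obs] <- 0
      num_p[k, ] <- colSums(a_term)
      den_p[k, ] <- colSums(a_term) + colSums(b_term)
      q_new[, k] <- rowSums(a_term + b_term)
    }
    P <- num_p / pmax(den_p, .Machine$double.eps)
    P <- pmin(pmax(P, eps), 1 - eps)
    Q <- q_new / two_nonmiss
    Q <- Q / rowSums(Q)                      # guard against roundoff
    ll <- loglik(Q %*% P)
    trace <- c(trace, ll)
    if (it > 1L && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  dimnames(Q) <- list(rownames(G), paste0("K", seq_len(K)))
  dimnames(P) <- list(paste0("K", seq_len(K)), colnames(G))
  structure(list(K = K, Q = Q, P = P, loglik = trace[length(trace)],
                 loglik_trace = trace, iterations = length(trace),
                 converged = converged, seed = seed),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, ",", nrow(x$Q), "accessions,",
      ncol(x$P), "loci\n")
  cat("log-likelihood:", format(x$loglik), "after", x$iterations,
      "EM iterations (", if (x$converged) "converged" else "iteration cap",
      ")\n")
  invisible(x)
}

#' Evanno delta-K table from replicate log-likelihoods
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' using per-K replicate means for the second difference and the
#' replicate standard deviation of `L(K)`. Defined only at interior K
#' with at least 2 replicates and `sd > 0`; undefined entries are `NA`.
#'
#' @param ll_by_k named list: `K` value -> numeric vector of replicate
#'   log-likelihoods (consecutive K values).
#' @return data frame with `K`, `n_reps`, `mean_ll`, `sd_ll`, `delta_k`.
#' @export
evanno_delta_k <- function(ll_by_k) {
  ks <- sort(as.integer(names(ll_by_k)))
  if (any(diff(ks) != 1L))
    stop("evanno_delta_k: K values must be consecutive")
  m <- vapply(as.character(ks), function(k) mean(ll_by_k[[k]]), 0)
  s <- vapply(as.character(ks), function(k) stats::sd(ll_by_k[[k]]), 0)
  nr <- vapply(as.character(ks), function(k) length(ll_by_k[[k]]), 0L)
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    if (i == 1L || i == length(ks)) next
    if (nr[i] < 2L || is.na(s[i]) || s[i] == 0) next
    dk[i] <- abs(m[i + 1L] - 2 * m[i] + m[i - 1L]) / s[i]
  }
  data.frame(K = ks, n_reps = nr, mean_ll = unname(m), sd_ll = unname(s),
             delta_k = dk)
}

#' Replicate admixture scan over a range of K with delta-K selection
#'
#' Runs [em_admixture()] for every (K, replicate) pair with derived
#' seeds, keeps the best-likelihood fit per K, builds the Evanno
#' delta-K table, and assigns each accession to its maximum-Q group in
#' the best fit of each K.
#'
#' @param genotypes a [genotype_matrix()].
#' @param k_range integer vector of consecutive K values.
#' @param replicates EM restarts per K (>= 2 for delta-K).
#' @param seed base seed; replicate seeds are derived from it.
#' @param ... passed to [em_admixture()].
#' @return object of class `structure_scan`: `fits` (best per K),
#'   `delta_k` (data frame; empty when `length(k_range) < 3`),
#'   `assignments` (accession x K matrix of max-Q groups), `ll_by_k`.
#' @export
structure_scan <- function(genotypes, k_range, replicates = 10L, seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  fits <- list(); ll_by_k <- list()
  for (K in k_range) {
    best <- NULL; lls <- numeric(replicates)
    for (r in seq_len(replicates)) {
      fit <- em_admixture(genotypes, K, seed = derive_seed(seed, K * 1000L + r), ...)
      lls[r] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fits[[as.character(K)]] <- best
    ll_by_k[[as.character(K)]] <- lls
  }
  dk <- if (length(k_range) >= 3L && replicates >= 2L && all(diff(k_range) == 1L))
    evanno_delta_k(ll_by_k)
  else
    data.frame(K = integer(0), n_reps = integer(0), mean_ll = numeric(0),
               sd_ll = numeric(0), delta_k = numeric(0))
  assign_mat <- vapply(fits, function(f) max.col(f$Q, ties.method = "first"),
                       integer(nrow(genotypes$calls)))
  if (is.null(dim(assign_mat)))
    assign_mat <- matrix(assign_mat, ncol = length(fits))
  dimnames(assign_mat) <- list(rownames(genotypes$calls), names(fits))
  structure(list(fits = fits, delta_k = dk, assignments = assign_mat,
                 ll_by_k = ll_by_k, seed = seed),
            class = "structure_scan")
}

#' @export
print.structure_scan <- function(x, ...) {
  cat("structure_scan over K =", paste(names(x$fits), collapse = ", "), "\n")
  if (nrow(x$delta_k)) {
    best <- x$delta_k$K[which.max(x$delta_k$delta_k)]
    cat("delta-K peak at K =", best, "\n")
  }
  invisible(x)
}

#' Match admixture cluster labels between two fits
#'
#' Admixture components are identifiable only up to label permutation.
#' Finds the column permutation of `Q2` maximising the summed Q overlap
#' with `Q1` (exhaustive over permutations; K here is small).
#'
#' @param Q1,Q2 accession x K admixture matrices with equal dimensions.
#' @return integer permutation `perm` such that `Q2[, perm]` aligns with `Q1`.
#' @export
match_admixture_labels <- function(Q1, Q2) {
  stopifnot(identical(dim(Q1), dim(Q2)))
  K <- ncol(Q1)
  overlap <- crossprod(Q1, Q2)   # K x K summed products
  perms <- permutations_of(K)
  scores <- vapply(perms, function(pm) sum(overlap[cbind(seq_len(K), pm)]), 0)
  perms[[which.max(scores)]]
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (pm in sub) for (pos in seq_len(k)) out[[length(out) + 1L]] <- append(pm, k, after = pos - 1L)
  out
}
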