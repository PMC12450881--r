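# SSR population genetics: allele frequencies, diversity statistics,
# Nei (1972) identity/distance, and report tables.

#' Allele frequencies per locus (pooled and/or per population)
#'
#' For a biallelic codominant locus the A-allele frequency is
#' `p(A) = (2 n_AA + n_AB) / (2 n)` over the `n` individuals with a
#' non-missing call; missing calls are excluded. Loci with no calls in a
#' group are omitted with a warning.
#'
#' @param genotypes a [genotype_matrix()].
#' @param by_population also compute per-population frequencies (requires
#'   population labels).
#' @return object of class `allele_freq_table`: a data frame with columns
#'   `locus`, `group` (`"pooled"` or a population), `p_A`, `p_B`, `n`.
#' @export
allele_frequencies <- function(genotypes, by_population = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  groups <- list(pooled = rownames(genotypes$calls))
  if (by_population) {
    if (is.null(genotypes$populations))
      stop("allele_frequencies: no population labels present")
    pops <- split(names(genotypes$populations), genotypes$populations)
    groups <- c(groups, pops)
  }
  rows <- list()
  for (g in names(groups)) {
    sub <- genotypes$calls[groups[[g]], , drop = FALSE]
    for (loc in colnames(sub)) {
      calls <- sub[, loc]
      calls <- calls[!is.na(calls)]
      n <- length(calls)
      if (n == 0L) {
        warning("allele_frequencies: locus ", loc, " has no calls in group ",
                g, "; omitted")
        next
      }
      pA <- (2 * sum(calls == "AA") + sum(calls == "AB")) / (2 * n)
      rows[[length(rows) + 1L]] <-
        data.frame(locus = loc, group = g, p_A = pA, p_B = 1 - pA, n = n,
                   stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("allele_freq_table", "data.frame"))
}

#' Effective number of alleles
#' @param p allele frequency vector (sums to 1).
#' @return `Ne = 1 / sum(p^2)`.
#' @export
effective_alleles <- function(p) {
  p <- check_freq(p)
  1 / sum(p^2)
}

#' Nei's gene diversity (expected heterozygosity, no sample correction)
#' @param p allele frequency vector.
#' @return `h = 1 - sum(p^2)`.
#' @export
nei_gene_diversity <- function(p) {
  p <- check_freq(p)
  1 - sum(p^2)
}

#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, computed via the
#' closed form `1 - S2 - S2^2 + S4` with `S2 = sum(p^2)`, `S4 = sum(p^4)`.
#'
#' @param p allele frequency vector.
#' @return the PIC value.
#' @export
pic <- function(p) {
  p <- check_freq(p)
  s2 <- sum(p^2); s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Observed and expected heterozygosity at a locus
#'
#' `Ho` is the fraction of non-missing calls that are heterozygous,
#' `Nei_h = 1 - sum(p^2)` the gene diversity, and
#' `He = 2n/(2n - 1) * Nei_h` the unbiased expected heterozygosity
#' (Levene's correction with `n` = individuals with non-missing calls).
#'
#' @param calls character vector of `AA`/`AB`/`BB`/`NA` calls at one locus.
#' @return list with `Ho`, `He` (`NA` with a flag when `n < 2`), `Nei_h`,
#'   `n`, `p_A`.
#' @export
heterozygosities <- function(calls) {
  calls <- calls[!is.na(calls)]
  n <- length(calls)
  if (n == 0L) stop("heterozygosities: no non-missing calls")
  pA <- (2 * sum(calls == "AA") + sum(calls == "AB")) / (2 * n)
  p <- c(pA, 1 - pA)
  nei_h <- 1 - sum(p^2)
  list(Ho = mean(calls == "AB"),
       He = if (n >= 2L) 2 * n / (2 * n - 1) * nei_h else NA_real_,
       He_defined = n >= 2L,
       Nei_h = nei_h, n = n, p_A = pA)
}

#' Nei (1972) genetic identity and distance between two populations
#'
#' Averages `sum(x*y)`, `sum(x^2)` and `sum(y^2)` over the shared loci
#' before forming the ratio: `I_N = J_XY / sqrt(J_X * J_Y)` and
#' `D = -ln(I_N)` (the convention of the standard population-genetics
#' software for codominant data).
#'
#' @param fx,fy named lists (by locus) of allele frequency vectors for
#'   the two populations; only shared locus names are used.
#' @return list with `identity`, `distance`, `n_loci`.
#' @export
nei_identity <- function(fx, fy) {
  shared <- intersect(names(fx), names(fy))
  if (!length(shared)) stop("nei_identity: no shared loci")
  jxy <- mean(vapply(shared, function(l) sum(fx[[l]] * fy[[l]]), 0))
  jx <- mean(vapply(shared, function(l) sum(fx[[l]]^2), 0))
  jy <- mean(vapply(shared, function(l) sum(fy[[l]]^2), 0))
  i_n <- jxy / sqrt(jx * jy)
  if (i_n <= 0) stop("nei_identity: non-positive identity (degenerate input)")
  list(identity = i_n, distance = -log(i_n), n_loci = length(shared))
}

freq_list_by_group <- function(freqs, group) {
  sub <- freqs[freqs$group == group, ]
  stats::setNames(lapply(seq_len(nrow(sub)), function(i) c(sub$p_A[i], sub$p_B[i])),
                  sub$locus)
}

#' Pairwise Nei identity and distance matrices over populations
#'
#' @param genotypes a [genotype_matrix()] with population labels.
#' @return list of class `population_identity` with symmetric matrices
#'   `identity` (unit diagonal) and `distance` (a [distance_matrix()]).
#' @export
nei_identity_matrix <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(genotypes$populations))
    stop("nei_identity_matrix: population labels are required")
  freqs <- allele_frequencies(genotypes, by_population = TRUE)
  pops <- unique(genotypes$populations)
  k <- length(pops)
  idm <- matrix(1, k, k, dimnames = list(pops, pops))
  dm <- matrix(0, k, k, dimnames = list(pops, pops))
  fl <- lapply(pops, function(p) freq_list_by_group(freqs, p))
  names(fl) <- pops
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    nd <- nei_identity(fl[[i]], fl[[j]])
    idm[i, j] <- idm[j, i] <- nd$identity
    dm[i, j] <- dm[j, i] <- nd$distance
  }
  structure(list(identity = idm, distance = distance_matrix(dm)),
            class = "population_identity")
}

#' @export
print.population_identity <- function(x, ...) {
  cat("population_identity over", nrow(x$identity), "populations\n")
  m <- x$identity
  m[lower.tri(m)] <- x$distance[lower.tri(m)]
  diag(m) <- NA
  cat("(identity above diagonal, distance below)\n")
  print(round(m, 4))
  invisible(x)
}

#' Invert a biallelic Nei gene diversity to allele frequencies
#'
#' For a biallelic locus `h = 2pq` determines the frequencies up to
#' label order: `p = (1 + sqrt(1 - 2h)) / 2`. This is the standard
#' reconstruction used to audit published per-locus diversity tables.
#'
#' @param h Nei gene diversity value(s) in `[0, 0.5]`.
#' @return matrix with columns `p` (major) and `q` (minor allele frequency).
#' @export
invert_nei_biallelic <- function(h) {
  h <- as.numeric(h)
  if (any(h < 0 | h > 0.5 + 1e-12))
    stop("invert_nei_biallelic: biallelic gene diversity must be in [0, 0.5]")
  p <- (1 + sqrt(pmax(1 - 2 * h, 0))) / 2
  cbind(p = p, q = 1 - p)
}

#' Per-locus genetic diversity table
#'
#' One row per locus pooled over populations — observed alleles `Na`,
#' effective alleles `Ne`, Shannon index `I`, observed heterozygosity
#' `Ho`, unbiased expected heterozygosity `He`, Nei's gene diversity
#' `Nei`, and `PIC` — followed by `Mean` and `St.Dev` rows.
#'
#' @param genotypes a [genotype_matrix()].
#' @return data frame with columns `locus`, `Na`, `Ne`, `I`, `Ho`, `He`,
#'   `Nei`, `PIC`; the last two rows are `Mean` and `St.Dev`.
#' @export
locus_table <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  loci <- colnames(genotypes$calls)
  rows <- lapply(loci, function(loc) {
    het <- heterozygosities(genotypes$calls[, loc])
    p <- c(het$p_A, 1 - het$p_A)
    data.frame(locus = loc, Na = sum(p > 0), Ne = effective_alleles(p),
               I = shannon_weaver(p), Ho = het$Ho, He = het$He,
               Nei = het$Nei_h, PIC = pic(p), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1L]
  tab <- rbind(tab,
               data.frame(locus = "Mean", t(colMeans(num)), stringsAsFactors = FALSE),
               data.frame(locus = "St.Dev", t(apply(num, 2, stats::sd)),
                          stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  tab
}

#' Per-population genetic diversity table
#'
#' For each population: mean and sd across loci of `Na`, `Ne`, `I`, `Ho`,
#' `He` and `Nei` (loci with no calls in a population are skipped), plus
#' the mean `PIC`.
#'
#' @param genotypes a [genotype_matrix()] with population labels.
#' @return data frame, one row per population.
#' @export
population_table <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(genotypes$populations))
    stop("population_table: population labels are required")
  pops <- unique(genotypes$populations)
  rows <- lapply(pops, function(pp) {
    ids <- names(genotypes$populations)[genotypes$populations == pp]
    sub <- genotype_matrix(genotypes$calls[ids, , drop = FALSE])
    per <- suppressWarnings(locus_table(sub))
    per <- per[!per$locus %in% c("Mean", "St.Dev"), ]
    data.frame(population = pp,
               Na = mean(per$Na), Na_sd = stats::sd(per$Na),
               Ne = mean(per$Ne), Ne_sd = stats::sd(per$Ne),
               I = mean(per$I), I_sd = stats::sd(per$I),
               Ho = mean(per$Ho), Ho_sd = stats::sd(per$Ho),
               He = mean(per$He), He_sd = stats::sd(per$He),
               Nei = mean(per$Nei), Nei_sd = stats::sd(per$Nei),
               PIC = mean(per$PIC), n = length(ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_freq <- function(p, tol = 1e-9) {
  p <- as.numeric(p)
  if (anyNA(p)) stop("allele frequencies contain NA")
  if (any(p < 0)) stop("negative allele frequency")
  s <- sum(p)
  if (abs(s - 1) > tol) stop("allele frequencies sum to ", format(s), ", not 1")
  p / s
}
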