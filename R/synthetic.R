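# Synthetic phenotype and structured SSR genotype generators. Defaults
# emulate the study conditions of the bundled reference tables: a
# 1,582-accession x 22-trait phenotype panel and a 147-accession x
# 15-locus genotype panel split over 6 regional populations.

#' Default trait specification for the proso millet phenotype panel
#'
#' Assembles the generator configuration from the bundled reference
#' tables: per-trait means and standard deviations (from the published
#' CVs) for the 12 quantitative traits, class probabilities for the 10
#' qualitative traits, and the published correlation matrix among the
#' eight quantitative traits it covers (other pairs independent).
#'
#' @return list with elements `quantitative` (data frame `trait`,
#'   `abbrev`, `unit`, `mean`, `sd`), `qualitative` (named list of class
#'   probability vectors) and `correlation` (matrix over all
#'   quantitative traits).
#' @export
proso_trait_specs <- function() {
  ref <- trait_reference()
  qn <- ref[ref$kind == "quantitative", ]
  qn$sd <- qn$mean * qn$cv_percent / 100
  cls <- trait_class_reference()
  ql <- split(cls, cls$trait)
  qualitative <- lapply(ql, function(d)
    stats::setNames(d$frequency, d$label)[order(d$class)])
  corr_ref <- trait_correlation_reference()
  p <- nrow(qn)
  corr <- diag(p)
  dimnames(corr) <- list(qn$abbrev, qn$abbrev)
  shared <- intersect(qn$abbrev, rownames(corr_ref))
  corr[shared, shared] <- corr_ref[shared, shared]
  list(quantitative = qn[, c("trait", "abbrev", "unit", "mean", "sd")],
       qualitative = qualitative[ref$trait[ref$kind == "qualitative"]],
       correlation = corr)
}

#' Generate a synthetic phenotype table
#'
#' Quantitative traits are drawn from a multivariate normal with the
#' requested means, standard deviations and correlation structure
#' (repaired to the nearest positive semi-definite matrix when needed);
#' qualitative traits are drawn categorically with the requested class
#' probabilities (codes 1..k). By default values are not truncated, so
#' sample means and CVs track the specification; `truncate_at_zero`
#' clamps negative draws for strictly positive measurements at the cost
#' of a small upward mean bias.
#'
#' @param n number of accessions.
#' @param specs trait specification as from [proso_trait_specs()].
#' @param seed integer seed; fixed seed gives identical output.
#' @param truncate_at_zero clamp negative quantitative draws to 0.
#' @return a [trait_matrix()] (`n` x 22 under the default specs).
#' @export
gen_phenotypes <- function(n = 1582L, specs = proso_trait_specs(), seed = 1L,
                           truncate_at_zero = FALSE) {
  qn <- specs$quantitative
  corr <- specs$correlation
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("gen_phenotypes: correlation matrix must be symmetric")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("gen_phenotypes: correlation matrix is not positive semi-definite")
  if (min(ev) < 1e-10)
    corr <- as.matrix(Matrix::nearPD(corr, corr = TRUE)$mat)
  ids <- sprintf("Acc%04d", seq_len(n))
  p <- nrow(qn)
  vals <- with_seed(derive_seed(seed, 1L), {
    z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = corr)
    sweep(sweep(z, 2, qn$sd, "*"), 2, qn$mean, "+")
  })
  if (truncate_at_zero) vals[vals < 0] <- 0
  qual_vals <- with_seed(derive_seed(seed, 2L), {
    vapply(specs$qualitative, function(prob)
      sample.int(length(prob), n, replace = TRUE, prob = prob),
      integer(n))
  })
  values <- cbind(vals, qual_vals)
  dimnames(values) <- list(ids, c(qn$trait, names(specs$qualitative)))
  trait_matrix(values,
               kinds = c(rep("quantitative", p),
                         rep("qualitative", length(specs$qualitative))),
               units = c(qn$unit, rep("code", length(specs$qualitative))))
}

#' Default regional population sizes for the genotype panel
#' @return named integer vector of per-population accession counts
#'   (147 accessions over six regions).
#' @export
proso_population_sizes <- function() {
  c(IMR = 14L, NER = 30L, NR = 10L, NWR = 25L, LPR = 63L, Abroad = 5L)
}

#' Generate structured SSR genotypes with known truth
#'
#' Balding-Nichols divergence model: each locus draws an ancestral
#' allele frequency `p ~ Uniform(ancestral_range)` (the default range
#' reaches close enough to fixation that pooled locus gene diversities
#' cover the span seen in published SSR panels, roughly 0.03-0.49) and
#' each population a
#' frequency from `Beta(p (1-F)/F, (1-p) (1-F)/F)` with `F = f_div`, so
#' population frequencies have mean `p` and variance `f_div * p (1-p)`.
#' Ancestry rows `Q` are one-hot population indicators by default, or
#' Dirichlet(`alpha`) draws for admixed individuals. Genotypes at
#' individual frequency `f = Q %*% P` are sampled with a heterozygote
#' deficit controlled by the inbreeding coefficient:
#' `P(AB) = 2 f (1-f) (1 - f_is)` (proso millet is predominantly
#' self-pollinating, hence the high default).
#'
#' @param pop_sizes named vector of per-population sizes.
#' @param n_loci number of biallelic loci.
#' @param f_div divergence parameter in (0, 1).
#' @param f_is inbreeding coefficient in `[0, 1]`.
#' @param alpha `NULL` for one-hot ancestry, or a Dirichlet
#'   concentration (scalar or length-K vector) for admixed rows.
#' @param ancestral_range range of ancestral allele frequencies.
#' @param locus_names optional locus names (default `L01`, `L02`, ...).
#' @param seed integer seed.
#' @return list with `genotypes` (a [genotype_matrix()] with population
#'   labels), `Q` (true ancestry rows), `P` (population x locus allele-A
#'   frequencies), `ancestral` (per-locus ancestral frequencies).
#' @export
gen_structured_genotypes <- function(pop_sizes = proso_population_sizes(),
                                     n_loci = 15L, f_div = 0.15, f_is = 0.8,
                                     alpha = NULL,
                                     ancestral_range = c(0.05, 0.95),
                                     locus_names = NULL, seed = 1L) {
  if (f_div <= 0 || f_div >= 1) stop("gen_structured_genotypes: f_div must be in (0, 1)")
  if (f_is < 0 || f_is > 1) stop("gen_structured_genotypes: f_is must be in [0, 1]")
  if (is.null(names(pop_sizes)))
    names(pop_sizes) <- paste0("Pop", seq_along(pop_sizes))
  K <- length(pop_sizes)
  n <- sum(pop_sizes)
  if (is.null(locus_names)) locus_names <- sprintf("L%02d", seq_len(n_loci))
  pops <- rep(names(pop_sizes), pop_sizes)
  ids <- sprintf("Acc%03d", seq_len(n))
  ancestral <- with_seed(derive_seed(seed, 11L),
                         stats::runif(n_loci, ancestral_range[1L], ancestral_range[2L]))
  P <- with_seed(derive_seed(seed, 12L), {
    shape <- (1 - f_div) / f_div
    m <- matrix(0, K, n_loci)
    for (l in seq_len(n_loci))
      m[, l] <- stats::rbeta(K, ancestral[l] * shape, (1 - ancestral[l]) * shape)
    m
  })
  dimnames(P) <- list(names(pop_sizes), locus_names)
  Q <- if (is.null(alpha)) {
    m <- matrix(0, n, K); m[cbind(seq_len(n), match(pops, names(pop_sizes)))] <- 1; m
  } else {
    a <- if (length(alpha) == 1L) rep(alpha, K) else alpha
    with_seed(derive_seed(seed, 13L), {
      g <- matrix(stats::rgamma(n * K, shape = rep(a, each = n)), n, K)
      g / rowSums(g)
    })
  }
  dimnames(Q) <- list(ids, names(pop_sizes))
  f <- Q %*% P
  calls <- with_seed(derive_seed(seed, 14L), {
    u <- matrix(stats::runif(n * n_loci), n, n_loci)
    p_aa <- f^2 + f_is * f * (1 - f)
    p_ab <- 2 * f * (1 - f) * (1 - f_is)
    ifelse(u < p_aa, "AA", ifelse(u < p_aa + p_ab, "AB", "BB"))
  })
  dimnames(calls) <- list(ids, locus_names)
  list(genotypes = genotype_matrix(calls, populations = stats::setNames(pops, ids)),
       Q = Q, P = P, ancestral = ancestral)
}

#' Write a deterministic bundle of synthetic CSV fixtures
#'
#' Produces, under `dir`: a 1,582 x 22 trait table with its schema, a
#' 147 x 15 genotype table with populations and the matching band
#' matrix, a 20-accession screening panel of band scores, accession
#' metadata for molecular IDs, and a manifest of MD5 checksums. The
#' same seed yields byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_traits_accessions rows of the phenotype table.
#' @return invisibly, a data frame `file`/`md5` (also written as
#'   `manifest.csv`).
#' @export
gen_fixture_suite <- function(dir, seed = 1L, n_traits_accessions = 1582L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("gen_fixture_suite: cannot write to ", dir)
  paths <- file.path(dir, c(traits = "traits.csv", schema = "traits_schema.csv",
                            geno = "genotypes.csv", pops = "populations.csv",
                            bands = "bands.csv", panel = "screening_panel_bands.csv",
                            meta = "metadata.csv"))
  names(paths) <- c("traits", "schema", "geno", "pops", "bands", "panel", "meta")
  traits <- gen_phenotypes(n = n_traits_accessions, seed = derive_seed(seed, 21L))
  write_trait_matrix(traits, paths["traits"], schema_path = paths["schema"])
  sim <- gen_structured_genotypes(seed = derive_seed(seed, 22L),
                                  locus_names = ssr_locus_reference()$locus)
  write_genotype_matrix(sim$genotypes, paths["geno"], populations_path = paths["pops"])
  write_band_matrix(genotype_to_band(sim$genotypes), paths["bands"])
  panel <- gen_structured_genotypes(pop_sizes = c(panel = 20L),
                                    seed = derive_seed(seed, 23L),
                                    locus_names = ssr_locus_reference()$locus)
  write_band_matrix(genotype_to_band(panel$genotypes), paths["panel"])
  ids <- accessions(sim$genotypes)
  meta <- data.frame(accession = ids,
                     Name = ids,
                     Unicode = sprintf("PM%04d", seq_along(ids)),
                     Source = unname(sim$genotypes$populations[ids]),
                     Classification = ifelse(sim$genotypes$populations[ids] == "Abroad",
                                             "foreign", "landrace"),
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, paths["meta"], row.names = FALSE, quote = FALSE)
  md5 <- tools::md5sum(unname(paths))
  manifest <- data.frame(file = basename(names(md5)), md5 = unname(md5),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
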