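calls_gm <- function(..., loci = NULL) {
  cols <- list(...)
  if (is.null(loci)) loci <- paste0("L", seq_along(cols))
  m <- do.call(cbind, cols)
  dimnames(m) <- list(paste0("a", seq_len(nrow(m))), loci)
  genotype_matrix(m)
}

test_that("allele frequencies follow the codominant counting rule", {
  gm <- calls_gm(cbind(c("AA", "AA", "AB", "BB")))
  af <- allele_frequencies(gm)
  expect_equal(af$p_A, 5 / 8)
  expect_equal(allele_frequencies(calls_gm(cbind(rep("AA", 4))))$p_A, 1)
  expect_equal(allele_frequencies(calls_gm(cbind(rep("AB", 4))))$p_A, 0.5)
  # missing calls are excluded from n
  gm2 <- calls_gm(cbind(c("AA", NA, "AB", NA)))
  af2 <- allele_frequencies(gm2)
  expect_equal(af2$n, 2)
  expect_equal(af2$p_A, 3 / 4)
})

test_that("per-population frequencies partition the data", {
  sim <- gen_structured_genotypes(pop_sizes = c(X = 8, Y = 6), n_loci = 4, seed = 3)
  af <- allele_frequencies(sim$genotypes, by_population = TRUE)
  expect_setequal(unique(af$group), c("pooled", "X", "Y"))
  pooled <- af[af$group == "pooled", ]
  byp <- af[af$group != "pooled", ]
  for (l in unique(af$locus)) {
    sub <- byp[byp$locus == l, ]
    expect_equal(sum(sub$p_A * sub$n) / sum(sub$n),
                 pooled$p_A[pooled$locus == l])
  }
})

test_that("effective alleles and Shannon index match the published table rows", {
  # reconstruct frequencies from published biallelic gene diversities
  p79 <- invert_nei_biallelic(0.4904)
  expect_lt(abs(effective_alleles(p79) - 1.9625), 0.002)
  p27 <- invert_nei_biallelic(0.4342)
  expect_lt(abs(shannon_weaver(p27) - 0.6259), 0.001)
  expect_equal(effective_alleles(1), 1)
  expect_equal(effective_alleles(rep(0.25, 4)), 4)
  expect_equal(shannon_weaver(c(0.5, 0.5)), log(2))
})

test_that("Ne = 1/(1 - h) identity holds to machine precision", {
  set.seed(21)
  for (i in 1:50) {
    p <- random_freqs(sample(2:6, 1))
    expect_equal(effective_alleles(p), 1 / (1 - nei_gene_diversity(p)),
                 tolerance = 1e-12)
  }
})

test_that("heterozygosities: observed fraction, Levene correction, flags", {
  h <- heterozygosities(rep("AB", 10))
  expect_equal(h$Ho, 1)
  expect_equal(h$Nei_h, 0.5)
  # p = (0.5, 0.5) with n = 50: He = (100/99) * 0.5
  calls <- c(rep("AA", 25), rep("BB", 25))
  h2 <- heterozygosities(calls)
  expect_equal(h2$He, 100 / 99 * 0.5, tolerance = 1e-12)
  h3 <- heterozygosities(rep("AA", 5))
  expect_equal(h3$Ho, 0); expect_equal(h3$Nei_h, 0)
  h4 <- heterozygosities("AB")
  expect_true(is.na(h4$He)); expect_false(h4$He_defined)
})

test_that("PIC matches brute-force pair summation and known values", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  set.seed(8)
  for (i in 1:200) {
    p <- random_freqs(sample(2:5, 1))
    expect_equal(pic(p), pic_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("PIC never exceeds gene diversity nor the Shannon index", {
  set.seed(14)
  for (i in 1:50) {
    p <- random_freqs(sample(2:6, 1))
    h <- nei_gene_diversity(p)
    expect_lte(pic(p), h + 1e-12)
    expect_lte(h, shannon_weaver(p) + 1e-12)
  }
})

test_that("Nei identity/distance: identity cases, symmetry, one-locus closed form", {
  fx <- list(L1 = c(0.7, 0.3), L2 = c(0.2, 0.8))
  expect_equal(nei_identity(fx, fx)$identity, 1)
  expect_equal(nei_identity(fx, fx)$distance, 0)
  fy <- list(L1 = c(0.4, 0.6), L2 = c(0.9, 0.1))
  expect_equal(nei_identity(fx, fy)$distance, nei_identity(fy, fx)$distance)
  expect_gte(nei_identity(fx, fy)$distance, 0)
  # single locus, x fixed: I = p / sqrt(p^2 + q^2)
  p <- 0.6
  one <- nei_identity(list(L = c(1, 0)), list(L = c(p, 1 - p)))
  expect_equal(one$identity, p / sqrt(p^2 + (1 - p)^2), tolerance = 1e-12)
})

test_that("distance matrices over populations are consistent with pair calls", {
  sim <- gen_structured_genotypes(pop_sizes = c(A = 10, B = 12, C = 8),
                                  n_loci = 12, seed = 5)
  ni <- nei_identity_matrix(sim$genotypes)
  expect_equal(diag(ni$identity), c(A = 1, B = 1, C = 1))
  expect_equal(unclass(ni$distance), -log(ni$identity), ignore_attr = TRUE)
  expect_equal(ni$distance, t(ni$distance), ignore_attr = TRUE)
})

test_that("allele frequency estimates recover the truth within binomial bounds", {
  set.seed(31)
  n <- 10000; p_true <- 0.7
  g <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
              prob = c(p_true^2, 2 * p_true * (1 - p_true), (1 - p_true)^2))
  gm <- calls_gm(cbind(g))
  # 99% bound on the mean of 2n Bernoulli(p) draws
  expect_lt(abs(allele_frequencies(gm)$p_A - p_true), 0.015)
})

test_that("locus table layout and degenerate loci", {
  gm <- calls_gm(cbind(rep("AA", 6)), cbind(rep("AB", 6)),
                 loci = c("mono", "het"))
  tab <- locus_table(gm)
  expect_equal(tab$locus, c("mono", "het", "Mean", "St.Dev"))
  mono <- tab[tab$locus == "mono", ]
  expect_equal(mono$Ne, 1); expect_equal(mono$I, 0)
  expect_equal(mono$Ho, 0); expect_equal(mono$PIC, 0)
  het <- tab[tab$locus == "het", ]
  expect_equal(het$Ho, 1); expect_equal(het$Nei, 0.5)
  expect_equal(tab$Ne[3], mean(tab$Ne[1:2]))
})

test_that("population table gives one row per region with locus-wise mean and sd", {
  sim <- gen_structured_genotypes(seed = 9)
  pt <- population_table(sim$genotypes)
  expect_equal(nrow(pt), 6)
  expect_setequal(pt$population, names(proso_population_sizes()))
  expect_true(all(pt$Ne >= 1))
  expect_true(all(pt$Ho >= 0 & pt$Ho <= 1))
  expect_equal(pt$n, unname(proso_population_sizes()[pt$population]))
})
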