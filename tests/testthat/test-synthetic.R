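test_that("phenotype generator reproduces requested moments at study scale", {
  tm <- gen_phenotypes(n = 1582, seed = 1)
  s <- trait_summaries(tm)
  sh <- s[s$trait == "stem_height", ]
  expect_lt(abs(sh$mean - 129.57), 2)
  expect_lt(abs(sh$cv_percent - 20.09), 1.5)
  ic <- class_frequencies(tm, "inflorescence_color")
  expect_lt(max(abs(ic$frequency - c(0.965, 0.035))), 0.02)
})

test_that("zero-correlation specs yield near-zero sample correlations", {
  spec <- list(quantitative = data.frame(trait = paste0("t", 1:5),
                                         abbrev = paste0("t", 1:5),
                                         unit = "u", mean = 10, sd = 2),
               qualitative = list(),
               correlation = diag(5))
  dimnames(spec$correlation) <- list(spec$quantitative$abbrev,
                                     spec$quantitative$abbrev)
  tm <- gen_phenotypes(n = 1582, specs = spec, seed = 2)
  r <- trait_correlations(tm)$r
  expect_lt(max(abs(r[upper.tri(r)])), 0.07)   # 2.58/sqrt(n) bound
})

test_that("requested trait correlations are realised", {
  tm <- gen_phenotypes(n = 1582, seed = 3)
  r <- trait_correlations(tm)$r
  target <- trait_correlation_reference()
  abbrev <- proso_trait_specs()$quantitative
  got <- r[abbrev$trait[match(rownames(target), abbrev$abbrev)],
           abbrev$trait[match(colnames(target), abbrev$abbrev)]]
  expect_lt(max(abs(got - target)), 0.07)
  bad_spec <- list(quantitative = data.frame(trait = c("a", "b"), abbrev = c("a", "b"),
                                             unit = "u", mean = 1, sd = 1),
                   qualitative = list(),
                   correlation = matrix(c(1, 2, 2, 1), 2,
                                        dimnames = list(c("a", "b"), c("a", "b"))))
  expect_error(gen_phenotypes(n = 10, specs = bad_spec), "positive semi-definite")
})

test_that("generators are deterministic in the seed", {
  t1 <- gen_phenotypes(n = 50, seed = 9)
  t2 <- gen_phenotypes(n = 50, seed = 9)
  expect_identical(t1$values, t2$values)
  g1 <- gen_structured_genotypes(seed = 9)
  g2 <- gen_structured_genotypes(seed = 9)
  expect_identical(g1$genotypes$calls, g2$genotypes$calls)
  expect_identical(g1$P, g2$P)
})

test_that("Balding-Nichols draws have mean p and variance F*p*(1-p)", {
  # 2000 populations x 5 loci at a fixed ancestral p = 10,000 Beta draws
  n_pop <- 2000
  sim <- gen_structured_genotypes(pop_sizes = stats::setNames(rep(1L, n_pop),
                                                              sprintf("P%04d", 1:n_pop)),
                                  n_loci = 5, f_div = 0.2,
                                  ancestral_range = c(0.6, 0.6), seed = 12)
  draws <- as.vector(sim$P)
  n_pop <- length(draws)
  p <- 0.6; f <- 0.2
  se_mean <- sqrt(f * p * (1 - p) / n_pop)
  expect_lt(abs(mean(draws) - p), 3 * se_mean)
  v <- f * p * (1 - p)
  se_var <- sqrt(2 / n_pop) * v   # approximate se of a variance estimate
  expect_lt(abs(stats::var(draws) - v), 4 * se_var)
})

test_that("divergence and inbreeding limits behave as designed", {
  # large samples keep the finite-sample Nei distance floor below the bound
  low <- gen_structured_genotypes(pop_sizes = c(A = 200, B = 200), n_loci = 50,
                                  f_div = 1e-4, seed = 4)
  ni <- nei_identity_matrix(low$genotypes)
  expect_lt(ni$distance["A", "B"], 0.005)
  selfed <- gen_structured_genotypes(pop_sizes = c(A = 30), n_loci = 10,
                                     f_is = 1, seed = 5)
  tab <- locus_table(selfed$genotypes)
  expect_true(all(tab$Ho[1:10] == 0))
  expect_error(gen_structured_genotypes(f_div = 0), "f_div")
  expect_error(gen_structured_genotypes(f_is = 2), "f_is")
})

test_that("mean Nei distance grows with the divergence parameter", {
  mean_d <- vapply(c(0.01, 0.05, 0.15, 0.3), function(fd) {
    ds <- vapply(1:4, function(s) {
      sim <- gen_structured_genotypes(pop_sizes = c(A = 30, B = 30), n_loci = 40,
                                      f_div = fd, seed = 100 + s)
      nei_identity_matrix(sim$genotypes)$distance["A", "B"]
    }, 0)
    mean(ds)
  }, 0)
  expect_true(all(diff(mean_d) > 0))
})

test_that("default panel spans low- and high-diversity loci", {
  sim <- gen_structured_genotypes(seed = 7)
  tab <- locus_table(sim$genotypes)
  nei <- tab$Nei[1:15]
  expect_lt(min(nei), 0.15)
  expect_gt(max(nei), 0.40)
  expect_true(all(nei >= 0 & nei < 1))
})

test_that("admixture recovery closes the loop on generated structure", {
  sim <- gen_structured_genotypes(pop_sizes = c(A = 25, B = 25, C = 25),
                                  n_loci = 60, f_div = 0.3, f_is = 0,
                                  seed = 31)
  fit <- em_admixture(sim$genotypes, K = 3, seed = 32)
  truth <- max.col(sim$Q)
  est <- max.col(fit$Q)
  expect_gt(max_label_agreement(est, truth), 0.95)
})

test_that("fixture suite is byte-identical under one seed and loads cleanly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- gen_fixture_suite(d1, seed = 3, n_traits_accessions = 200)
  m2 <- gen_fixture_suite(d2, seed = 3, n_traits_accessions = 200)
  expect_identical(m1$md5, m2$md5)
  m3 <- gen_fixture_suite(withr::local_tempdir(), seed = 4, n_traits_accessions = 200)
  expect_false(identical(m1$md5, m3$md5))
  expect_no_warning({
    tm <- read_trait_matrix(file.path(d1, "traits.csv"),
                            file.path(d1, "traits_schema.csv"))
    gm <- read_genotype_matrix(file.path(d1, "genotypes.csv"),
                               populations = file.path(d1, "populations.csv"))
    bm <- read_band_matrix(file.path(d1, "bands.csv"))
    panel <- read_band_matrix(file.path(d1, "screening_panel_bands.csv"))
  })
  expect_equal(dim(tm$values), c(200, 22))
  expect_equal(dim(gm$calls), c(147, 15))
  expect_equal(nrow(panel$bands), 20)
  codes <- encode_fingerprint(bm)
  expect_gte(length(unique(codes)) / length(codes), 0.95)
})
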