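test_that("trait matrix round-trips through CSV and flags missing cells", {
  vals <- matrix(c(129.57, 101.2, 88.8, 1, 2, NA), nrow = 3,
                 dimnames = list(c("Hongruanmi", "Getami", "Mizi"),
                                 c("SH", "IC")))
  tm <- trait_matrix(vals, kinds = c(SH = "quantitative", IC = "qualitative"),
                     units = c(SH = "cm", IC = "code"))
  path <- withr::local_tempfile(fileext = ".csv")
  schema <- withr::local_tempfile(fileext = ".csv")
  write_trait_matrix(tm, path, schema_path = schema)
  back <- read_trait_matrix(path, schema)
  expect_equal(back$values, tm$values)
  expect_equal(back$kinds, tm$kinds)
  expect_true(is.na(back$values["Mizi", "IC"]))   # empty cell is NA, never 0
})

test_that("duplicate accession ids are rejected by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,SH", "Hongruanmi,1", "Getami,2", "Hongruanmi,3"), path)
  expect_error(read_trait_matrix(path, data.frame(trait = "SH", kind = "quantitative")),
               "Hongruanmi")
  expect_error(trait_matrix(matrix(1:2, 2, dimnames = list(c("a", "a"), "t")),
                            "quantitative"), "duplicate")
})

test_that("unparseable cells and qualitative code violations are named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,SH", "a,12.3", "b,oops"), path)
  expect_error(read_trait_matrix(path, data.frame(trait = "SH", kind = "quantitative")),
               "row 'b'.*column 'SH'")
  expect_error(trait_matrix(matrix(-1, 1, dimnames = list("a", "t")), "qualitative"),
               "non-negative integers")
})

test_that("band pair mapping covers all four patterns and inverts", {
  # column layout: P1.1 P1.2 P2.1 P2.2
  # P1 per accession: AA, BB, AB, missing; P2: AB, AA, BB, missing
  b <- cbind(c(1, 0, 1, 0), c(0, 1, 1, 0),
             c(1, 1, 0, 0), c(1, 0, 1, 0))
  rownames(b) <- paste0("a", 1:4)
  bm <- band_matrix(b, primer_names = c("P1", "P2"))
  gm <- band_to_genotype(bm)
  expect_equal(unname(gm$calls[, "P1"]), c("AA", "BB", "AB", NA))
  expect_equal(unname(gm$calls[, "P2"]), c("AB", "AA", "BB", NA))
  # inversion is the identity on all calls including the (0,0) missing rows
  expect_equal(genotype_to_band(gm)$bands, bm$bands)
})

test_that("band matrices demand exactly two slots per primer", {
  m <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_error(band_matrix(m, c("P1", "P2")), "2 band slots")
  expect_error(band_matrix(matrix(2, 2, 2, dimnames = list(c("a", "b"), NULL)), "P1"),
               "0 or 1")
})

test_that("genotype matrices validate calls and population partitions", {
  calls <- matrix(c("AA", "AB", "BB", NA), 2, 2,
                  dimnames = list(c("a", "b"), c("BLF-79", "BLF80")))
  gm <- genotype_matrix(calls, populations = c(a = "IMR", b = "NER"))
  expect_equal(colnames(gm$calls), c("BLF79", "BLF80"))  # hyphens stripped
  expect_error(genotype_matrix(matrix("AC", 1, 1, dimnames = list("a", "l"))),
               "invalid call")
  expect_error(genotype_matrix(calls, populations = c(a = "IMR")), "missing")
})

test_that("genotype and band CSV round trips are identities", {
  sim <- gen_structured_genotypes(pop_sizes = c(X = 6, Y = 4), n_loci = 5, seed = 2)
  gpath <- withr::local_tempfile(fileext = ".csv")
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_genotype_matrix(sim$genotypes, gpath, populations_path = ppath)
  back <- read_genotype_matrix(gpath, populations = ppath)
  expect_equal(back$calls, sim$genotypes$calls)
  expect_equal(back$populations, sim$genotypes$populations)
  bm <- genotype_to_band(sim$genotypes)
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_band_matrix(bm, bpath)
  expect_equal(read_band_matrix(bpath)$bands, bm$bands)
})

test_that("distance matrices enforce symmetry, zero diagonal, labels", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d <- distance_matrix(m)
  dpath <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(d, dpath)
  expect_equal(unclass(read_distance_matrix(dpath)), unclass(d))
  expect_error(distance_matrix(matrix(c(1, 1, 1, 0), 2, dimnames = list(c("A", "B"), NULL))),
               "diagonal")
  expect_error(distance_matrix(matrix(c(0, 2, 1, 0), 2, dimnames = list(c("A", "B"), NULL))),
               "symmetric")
})

test_that("newick serialization handles degenerate and forced forms", {
  single <- structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                           labels = "A"), class = "upgma_tree")
  expect_equal(write_newick(single), "A;")
  two <- upgma(distance_matrix(matrix(c(0, 1, 1, 0), 2,
                                      dimnames = list(c("A", "B"), c("A", "B")))))
  expect_equal(write_newick(two), "(A:0.5,B:0.5);")
  bad <- structure(list(merge = matrix(c(-1L, -2L), 1), height = 0.5,
                        labels = c("A", "")), class = "upgma_tree")
  expect_error(write_newick(bad), "labelled")
})

test_that("newick output re-parses to identical merge heights", {
  d <- random_distance(7, labels = paste0("t", 1:7))
  tr <- upgma(d)
  ph <- ape::read.tree(text = write_newick(tr))
  expect_setequal(ph$tip.label, tr$labels)
  coph_ape <- ape::cophenetic.phylo(ph)[tr$labels, tr$labels]
  expect_equal(coph_ape, tree_cophenetic(tr), tolerance = 1e-6)
})
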