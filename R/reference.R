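# Bundled published summary statistics for proso millet diversity
# panels: a 15-locus SSR diversity table and a 6-population Nei
# identity/distance table from a 147-accession panel, and per-trait
# means/CVs/class frequencies from a 1,582-accession phenotype study.
# They serve two roles: auditing the package's statistics against
# published values, and parameterising the synthetic-data generator so
# its defaults emulate realistic study conditions.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "germdiv")
  if (!nzchar(p)) stop("reference file not installed: ", file)
  p
}

#' Published per-locus SSR diversity reference table
#'
#' Summary statistics (Na, Ne, Shannon I, Ho, He, Nei's gene diversity,
#' PIC) for 15 polymorphic SSR loci scored on a 147-accession proso
#' millet panel.
#'
#' @return data frame with columns `locus`, `na`, `ne`, `i`, `ho`, `he`,
#'   `nei`, `pic`.
#' @export
ssr_locus_reference <- function() {
  utils::read.csv(ref_path("ssr_locus_reference.csv"), stringsAsFactors = FALSE)
}

#' Published pairwise Nei identity/distance reference table
#'
#' Nei (1972) genetic identity and distance between six regional proso
#' millet populations (Inner Mongolia, Northeast, Northern, Northwest,
#' Loess Plateau regions and abroad).
#'
#' @return data frame with columns `pop_a`, `pop_b`, `identity`,
#'   `distance` (15 unordered pairs).
#' @export
population_identity_reference <- function() {
  utils::read.csv(ref_path("population_identity_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' Published per-trait phenotype reference table
#'
#' Per-trait kind, unit, and (where published) mean, coefficient of
#' variation and Shannon-Weaver diversity index for the 22 traits (12
#' quantitative, 10 qualitative) of a 1,582-accession proso millet
#' phenotype study.
#'
#' @return data frame with columns `trait`, `abbrev`, `kind`, `unit`,
#'   `mean`, `cv_percent`, `diversity`.
#' @export
trait_reference <- function() {
  utils::read.csv(ref_path("trait_reference.csv"), stringsAsFactors = FALSE)
}

#' Qualitative trait class frequency reference
#'
#' Class frequencies for the 10 qualitative traits. Frequencies printed
#' in the source study are used as published; classes whose share was
#' not printed split the published remainder (documented in the methods
#' vignette).
#'
#' @return data frame with columns `trait`, `class`, `label`, `frequency`.
#' @export
trait_class_reference <- function() {
  utils::read.csv(ref_path("trait_class_reference.csv"), stringsAsFactors = FALSE)
}

#' Published quantitative trait correlation reference
#'
#' Pairwise correlations among eight quantitative traits (tiller number,
#' main stem nodes, panicle length, stem height, panicle/grain/straw
#' weight per plant, thousand-grain weight); non-significant pairs are 0.
#'
#' @return symmetric correlation matrix with trait abbreviations as
#'   dimnames.
#' @export
trait_correlation_reference <- function() {
  m <- as.matrix(utils::read.csv(ref_path("trait_correlation_reference.csv"),
                                 row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}
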