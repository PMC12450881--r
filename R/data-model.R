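#' germdiv: germplasm diversity analysis from traits and SSR markers
#'
#' Shared data containers used across the package:
#' \describe{
#'   \item{trait_matrix}{accession x trait phenotype table with per-trait
#'     kind (quantitative or qualitative) and units.}
#'   \item{band_matrix}{accession x band-slot binary scores, two slots per
#'     SSR primer (one per allele of a biallelic codominant locus).}
#'   \item{genotype_matrix}{accession x locus codominant calls
#'     (\code{"AA"}, \code{"AB"}, \code{"BB"} or \code{NA}) with an
#'     optional population partition.}
#'   \item{distance_matrix}{labelled square symmetric non-negative matrix
#'     with a zero diagonal.}
#' }
#'
#' @keywords internal
"_PACKAGE"

TRAIT_KINDS <- c("quantitative", "qualitative")

#' Construct a trait matrix
#'
#' An accession x trait phenotype table. Quantitative traits hold real
#' measurements in the stated unit; qualitative traits hold small
#' non-negative integer class codes. Missing values are `NA`, never 0.
#'
#' @param values numeric matrix (accessions in rows, traits in columns)
#'   with unique, non-empty rownames (accession ids) and colnames.
#' @param kinds character vector, one of `"quantitative"`/`"qualitative"`
#'   per trait, named by trait or in column order.
#' @param units optional character vector of per-trait units (free text).
#' @return an object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, kinds, units = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- rownames(values)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("trait_matrix: accession ids (rownames) are required")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("trait_matrix: duplicate accession id(s): ",
         paste(unique(dup), collapse = ", "))
  if (is.null(colnames(values)))
    stop("trait_matrix: trait names (colnames) are required")
  if (!is.null(names(kinds))) kinds <- kinds[colnames(values)]
  kinds <- match.arg(as.character(kinds), TRAIT_KINDS, several.ok = TRUE)
  if (length(kinds) != ncol(values))
    stop("trait_matrix: 'kinds' must declare every trait column")
  names(kinds) <- colnames(values)
  qual <- values[, kinds == "qualitative", drop = FALSE]
  bad <- !is.na(qual) & (qual < 0 | qual != round(qual))
  if (any(bad))
    stop("trait_matrix: qualitative codes must be non-negative integers (trait ",
         paste(unique(colnames(qual)[col(qual)[bad]]), collapse = ", "), ")")
  if (is.null(units)) units <- rep("", ncol(values))
  if (!is.null(names(units))) units <- units[colnames(values)]
  units <- as.character(units)
  names(units) <- colnames(values)
  structure(list(values = values, kinds = kinds, units = units),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x$values), "accessions x", ncol(x$values),
      "traits (", sum(x$kinds == "quantitative"), "quantitative,",
      sum(x$kinds == "qualitative"), "qualitative )\n")
  cat("missing cells:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Accession ids of a container
#' @param x a `trait_matrix`, `band_matrix` or `genotype_matrix`.
#' @return character vector of accession identifiers.
#' @export
accessions <- function(x) UseMethod("accessions")
#' @export
accessions.trait_matrix <- function(x) rownames(x$values)
#' @export
accessions.band_matrix <- function(x) rownames(x$bands)
#' @export
accessions.genotype_matrix <- function(x) rownames(x$calls)

#' Construct a band matrix
#'
#' Binary electrophoresis band scores with exactly two band slots per SSR
#' primer. Slot columns are named `<primer>.1` and `<primer>.2`. The slot
#' pair maps one-to-one onto codominant genotype calls:
#' (1,0) -> AA, (0,1) -> BB, (1,1) -> AB, (0,0) -> missing.
#'
#' @param bands 0/1 matrix, accessions in rows; either `2 * length(primers)`
#'   columns in primer order or columns already named `<primer>.1/.2`.
#' @param primer_names character vector of primer names.
#' @return an object of class `band_matrix`.
#' @export
band_matrix <- function(bands, primer_names) {
  bands <- as.matrix(bands)
  storage.mode(bands) <- "double"
  if (is.null(rownames(bands)) || any(rownames(bands) == ""))
    stop("band_matrix: accession ids (rownames) are required")
  if (anyDuplicated(rownames(bands)))
    stop("band_matrix: duplicate accession id(s): ",
         paste(unique(rownames(bands)[duplicated(rownames(bands))]), collapse = ", "))
  primer_names <- as.character(primer_names)
  if (ncol(bands) != 2L * length(primer_names))
    stop("band_matrix: expected exactly 2 band slots per primer (",
         2L * length(primer_names), " columns), got ", ncol(bands))
  if (any(!bands %in% c(0, 1)))
    stop("band_matrix: entries must be 0 or 1")
  colnames(bands) <- paste0(rep(primer_names, each = 2L), ".", 1:2)
  structure(list(bands = bands, primer_names = primer_names),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("band_matrix:", nrow(x$bands), "accessions x",
      length(x$primer_names), "primers (2 slots each)\n")
  invisible(x)
}

GENO_CALLS <- c("AA", "AB", "BB")

#' Construct a genotype matrix
#'
#' Codominant calls at biallelic SSR loci, with an optional partition of
#' the accessions into populations (for example geographic regions).
#'
#' @param calls character matrix of `"AA"`, `"AB"`, `"BB"` or `NA`
#'   (missing), accessions in rows, loci in columns; rownames and
#'   colnames required.
#' @param populations optional character/factor vector of population
#'   labels, named by accession or in row order.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, populations = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(rownames(calls)) || any(rownames(calls) == ""))
    stop("genotype_matrix: accession ids (rownames) are required")
  if (anyDuplicated(rownames(calls)))
    stop("genotype_matrix: duplicate accession id(s): ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (is.null(colnames(calls)))
    stop("genotype_matrix: locus names (colnames) are required")
  colnames(calls) <- normalize_locus_names(colnames(calls))
  bad <- !is.na(calls) & !calls %in% GENO_CALLS
  if (any(bad))
    stop("genotype_matrix: invalid call(s): ",
         paste(unique(calls[bad]), collapse = ", "))
  if (!is.null(populations)) {
    populations <- stats::setNames(as.character(populations), names(populations))
    if (!is.null(names(populations))) {
      miss <- setdiff(rownames(calls), names(populations))
      if (length(miss))
        stop("genotype_matrix: populations missing for: ",
             paste(miss, collapse = ", "))
      populations <- populations[rownames(calls)]
    } else if (length(populations) != nrow(calls)) {
      stop("genotype_matrix: 'populations' must label every accession")
    }
    if (anyNA(populations))
      stop("genotype_matrix: population labels must form a partition (no NA)")
    names(populations) <- rownames(calls)
  }
  structure(list(calls = calls, populations = populations),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "accessions x", ncol(x$calls), "loci\n")
  if (!is.null(x$populations)) {
    tab <- table(x$populations)
    cat("populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' Normalize SSR locus/primer names
#'
#' Hyphenated (`BLF-41`) and plain (`BLF41`) spellings of the same primer
#' are treated as one identifier: hyphens are stripped.
#'
#' @param x character vector of locus or primer names.
#' @return character vector with hyphens removed.
#' @export
normalize_locus_names <- function(x) gsub("-", "", as.character(x), fixed = TRUE)

#' Construct a labelled distance matrix
#'
#' @param m square numeric matrix, symmetric, non-negative, zero diagonal.
#' @param labels optional labels (default taken from dimnames).
#' @param tol symmetry/diagonal tolerance.
#' @return an object of class `distance_matrix` (a labelled base matrix).
#' @export
distance_matrix <- function(m, labels = NULL, tol = 1e-9) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance_matrix: matrix must be square")
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) stop("distance_matrix: labels are required")
  dimnames(m) <- list(labels, labels)
  if (any(abs(diag(m)) > tol)) stop("distance_matrix: diagonal must be 0")
  diag(m) <- 0
  if (max(abs(m - t(m))) > tol) stop("distance_matrix: matrix must be symmetric")
  m <- (m + t(m)) / 2
  if (any(m < -tol)) stop("distance_matrix: entries must be non-negative")
  m[m < 0] <- 0
  structure(m, class = c("distance_matrix", "matrix", "array"))
}

#' Convert band scores to codominant genotype calls
#'
#' Applies the slot-pair mapping (1,0) -> AA, (0,1) -> BB, (1,1) -> AB,
#' (0,0) -> missing at every primer; locus names inherit primer names.
#'
#' @param bands a [band_matrix()].
#' @param populations optional population labels passed through.
#' @return a [genotype_matrix()].
#' @export
band_to_genotype <- function(bands, populations = NULL) {
  stopifnot(inherits(bands, "band_matrix"))
  b <- bands$bands
  np <- length(bands$primer_names)
  calls <- matrix(NA_character_, nrow(b), np,
                  dimnames = list(rownames(b), bands$primer_names))
  for (j in seq_len(np)) {
    s1 <- b[, 2L * j - 1L]
    s2 <- b[, 2L * j]
    calls[, j] <- ifelse(s1 == 1 & s2 == 1, "AB",
                  ifelse(s1 == 1, "AA",
                  ifelse(s2 == 1, "BB", NA_character_)))
  }
  genotype_matrix(calls, populations = populations)
}

#' Convert genotype calls back to band scores
#'
#' Inverse of [band_to_genotype()]: AA -> (1,0), BB -> (0,1), AB -> (1,1),
#' missing -> (0,0).
#'
#' @param genotypes a [genotype_matrix()].
#' @return a [band_matrix()].
#' @export
genotype_to_band <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$calls
  b <- matrix(0, nrow(g), 2L * ncol(g), dimnames = list(rownames(g), NULL))
  for (j in seq_len(ncol(g))) {
    b[, 2L * j - 1L] <- as.numeric(g[, j] %in% c("AA", "AB"))
    b[, 2L * j]      <- as.numeric(g[, j] %in% c("BB", "AB"))
  }
  band_matrix(b, colnames(g))
}
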