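# Tabular IO. One CSV dialect throughout: comma separated, UTF-8, "."
# decimal, first column = accession id, header row present. Missing cells
# are empty or "NA" on read and written as "NA".

read_csv_strict <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column in ", path)
  ids <- as.character(df[[1L]])
  if (anyNA(ids) || any(ids == "")) stop("empty accession id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate accession id(s) in ", path, ": ", paste(dup, collapse = ", "))
  rownames(df) <- ids
  df[-1L]
}

write_csv_strict <- function(df, path, id_col = "accession") {
  out <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE), id_col),
               df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trait matrix from CSV
#'
#' @param path CSV file: first column accession id, one column per trait.
#' @param schema data frame (or path to a CSV) with columns `trait`,
#'   `kind` (`quantitative`/`qualitative`) and optionally `unit`,
#'   covering every trait column of `path`.
#' @return a [trait_matrix()].
#' @export
read_trait_matrix <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- utils::read.csv(schema, stringsAsFactors = FALSE)
  stopifnot(all(c("trait", "kind") %in% names(schema)))
  df <- read_csv_strict(path)
  miss <- setdiff(names(df), schema$trait)
  if (length(miss))
    stop("schema does not cover trait column(s): ", paste(miss, collapse = ", "))
  kinds <- stats::setNames(schema$kind, schema$trait)[names(df)]
  units <- if ("unit" %in% names(schema))
    stats::setNames(as.character(schema$unit), schema$trait)[names(df)] else NULL
  vals <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(rownames(df), names(df)))
  for (j in seq_along(df)) {
    raw <- df[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("unparseable cell at row '", rownames(df)[bad[1L]], "', column '",
           names(df)[j], "': '", raw[bad[1L]], "'")
    vals[, j] <- num
  }
  trait_matrix(vals, kinds = kinds, units = units)
}

#' Write a trait matrix (and its schema) to CSV
#' @param traits a [trait_matrix()].
#' @param path output CSV path for values.
#' @param schema_path optional path for the trait/kind/unit schema CSV.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(traits, path, schema_path = NULL) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (!is.null(schema_path))
    utils::write.csv(data.frame(trait = colnames(traits$values),
                                kind = unname(traits$kinds),
                                unit = unname(traits$units)),
                     schema_path, row.names = FALSE, quote = FALSE)
  write_csv_strict(as.data.frame(traits$values), path)
}

#' Read a band matrix from CSV
#'
#' Columns after the id column must be named `<primer>.1`/`<primer>.2`
#' in adjacent pairs.
#'
#' @param path CSV file.
#' @return a [band_matrix()].
#' @export
read_band_matrix <- function(path) {
  df <- read_csv_strict(path)
  cols <- names(df)
  primers <- unique(sub("\\.[12]$", "", cols))
  expect <- paste0(rep(primers, each = 2L), ".", 1:2)
  if (!identical(cols, expect))
    stop("band columns must be <primer>.1/<primer>.2 pairs; found: ",
         paste(utils::head(cols, 6L), collapse = ", "))
  band_matrix(as.matrix(df), primers)
}

#' Write a band matrix to CSV
#' @param bands a [band_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(bands, path) {
  stopifnot(inherits(bands, "band_matrix"))
  write_csv_strict(as.data.frame(bands$bands), path)
}

#' Read a genotype matrix from CSV
#' @param path CSV of `AA`/`AB`/`BB`/`NA` calls, first column accession id.
#' @param populations optional vector, or path to a two-column CSV
#'   (accession, population).
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, populations = NULL) {
  df <- read_csv_strict(path)
  if (is.character(populations) && length(populations) == 1L && file.exists(populations)) {
    pdf <- utils::read.csv(populations, stringsAsFactors = FALSE)
    populations <- stats::setNames(as.character(pdf[[2L]]), as.character(pdf[[1L]]))
  }
  genotype_matrix(as.matrix(df), populations = populations)
}

#' Write a genotype matrix to CSV
#' @param genotypes a [genotype_matrix()].
#' @param path output path for the calls.
#' @param populations_path optional path for the accession/population table.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(genotypes, path, populations_path = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is.null(populations_path) && !is.null(genotypes$populations))
    utils::write.csv(data.frame(accession = names(genotypes$populations),
                                population = unname(genotypes$populations)),
                     populations_path, row.names = FALSE, quote = FALSE)
  write_csv_strict(as.data.frame(genotypes$calls), path)
}

#' Read a labelled square distance matrix from CSV
#' @param path CSV whose first column and header carry the same labels.
#' @return a [distance_matrix()].
#' @export
read_distance_matrix <- function(path) {
  df <- read_csv_strict(path)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  distance_matrix(m, labels = rownames(df))
}

#' Write a labelled square distance matrix to CSV
#' @param dist a [distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path) {
  stopifnot(inherits(dist, "distance_matrix"))
  write_csv_strict(as.data.frame(unclass(dist)), path, id_col = "label")
}
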