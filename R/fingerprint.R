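# DNA fingerprint codes, minimal discriminating primer sets and
# molecular-ID payloads.

#' Encode per-accession DNA fingerprint strings
#'
#' Concatenates the two band bits of each primer in the given order, so
#' 12 primers yield a 24-character `'0'/'1'` string per accession.
#'
#' @param bands a [band_matrix()].
#' @param primer_order primers to encode, in order (default: all primers
#'   in matrix order). Hyphen variants of the same primer name are
#'   accepted.
#' @return named character vector of codes with attribute
#'   `primer_order`.
#' @export
encode_fingerprint <- function(bands, primer_order = NULL) {
  stopifnot(inherits(bands, "band_matrix"))
  have <- normalize_locus_names(bands$primer_names)
  if (is.null(primer_order)) primer_order <- bands$primer_names
  want <- normalize_locus_names(primer_order)
  unknown <- setdiff(want, have)
  if (length(unknown))
    stop("encode_fingerprint: unknown primer(s): ", paste(unknown, collapse = ", "))
  idx <- match(want, have)
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  b <- bands$bands[, cols, drop = FALSE]
  codes <- apply(b, 1L, function(r) paste(as.integer(r), collapse = ""))
  structure(codes, primer_order = want)
}

#' Decode a fingerprint string back to band scores
#'
#' Positional inverse of [encode_fingerprint()].
#'
#' @param code a `'0'/'1'` string of length `2 * length(primer_order)`.
#' @param primer_order primer names in encoding order.
#' @return named 0/1 vector over `<primer>.1/.2` slots.
#' @export
decode_fingerprint <- function(code, primer_order) {
  bits <- as.integer(strsplit(code, "")[[1L]])
  if (length(bits) != 2L * length(primer_order) || anyNA(bits) || any(!bits %in% 0:1))
    stop("decode_fingerprint: code must be ", 2L * length(primer_order),
         " characters of '0'/'1'")
  stats::setNames(bits, paste0(rep(normalize_locus_names(primer_order), each = 2L), ".", 1:2))
}

#' Greedy minimal discriminating primer set
#'
#' Implements the principle of distinguishing the maximum number of
#' accessions with the minimum number of primers: repeatedly add the
#' primer that splits the largest number of currently indistinguishable
#' accession pairs (ties broken by input primer order), stopping when no
#' primer adds discrimination.
#'
#' @param bands a [band_matrix()].
#' @return list with `primers` (selected, in selection order) and
#'   `report`: data frame of `step`, `primer`, `pairs_split`,
#'   `distinct_codes` after each step.
#' @export
minimal_primer_set <- function(bands) {
  stopifnot(inherits(bands, "band_matrix"))
  b <- bands$bands
  n <- nrow(b)
  if (n < 2L)
    return(list(primers = character(0),
                report = data.frame(step = integer(0), primer = character(0),
                                    pairs_split = integer(0),
                                    distinct_codes = integer(0))))
  primer_cols <- lapply(seq_along(bands$primer_names),
                        function(j) b[, c(2L * j - 1L, 2L * j), drop = FALSE])
  pattern <- vapply(primer_cols,
                    function(m) paste0(m[, 1L], m[, 2L]), character(n))
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = n)
  group <- rep(1L, n)            # current indistinguishability classes
  chosen <- integer(0)
  report <- list()
  repeat {
    remaining <- setdiff(seq_along(bands$primer_names), chosen)
    if (!length(remaining)) break
    gains <- vapply(remaining, function(j) {
      new_group <- paste(group, pattern[, j])
      pairs_before <- sum(choose(table(group), 2))
      pairs_after <- sum(choose(table(new_group), 2))
      pairs_before - pairs_after
    }, 0)
    if (max(gains) <= 0) break
    j <- remaining[which.max(gains)]   # which.max takes the first tie
    chosen <- c(chosen, j)
    group <- match(paste(group, pattern[, j]), unique(paste(group, pattern[, j])))
    report[[length(report) + 1L]] <-
      data.frame(step = length(chosen), primer = bands$primer_names[j],
                 pairs_split = as.integer(max(gains)),
                 distinct_codes = length(unique(group)),
                 stringsAsFactors = FALSE)
  }
  list(primers = bands$primer_names[chosen],
       report = if (length(report)) do.call(rbind, report)
                else data.frame(step = integer(0), primer = character(0),
                                pairs_split = integer(0),
                                distinct_codes = integer(0)))
}

ID_FIELDS <- c("Name", "Unicode", "Source", "Classification")

#' Build a molecular-ID payload for QR encoding
#'
#' Deterministic multi-line text combining the accession's metadata with
#' its fingerprint code — one `Field: value` line each for Name, Unicode,
#' Source, Classification and Code. The text is byte-identical across
#' runs and is what a QR encoder would render.
#'
#' @param code fingerprint string for one accession.
#' @param meta one-row data frame (or named list) with non-empty
#'   `Name`, `Unicode`, `Source`, `Classification` fields.
#' @return single character string (lines separated by `"\n"`).
#' @export
build_id_payload <- function(code, meta) {
  meta <- as.list(meta)
  for (f in ID_FIELDS) {
    val <- meta[[f]]
    if (is.null(val) || is.na(val) || !nzchar(as.character(val)))
      stop("build_id_payload: missing metadata field '", f, "'")
  }
  if (!nzchar(code)) stop("build_id_payload: empty fingerprint code")
  paste(c(paste0(ID_FIELDS, ": ", vapply(meta[ID_FIELDS], as.character, "")),
          paste0("Code: ", code)),
        collapse = "\n")
}

#' Parse a molecular-ID payload back to its fields
#' @param payload text produced by [build_id_payload()].
#' @return named list with the four metadata fields and `Code`.
#' @export
parse_id_payload <- function(payload) {
  lines <- strsplit(payload, "\n", fixed = TRUE)[[1L]]
  m <- regmatches(lines, regexec("^([A-Za-z]+): (.*)$", lines))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("parse_id_payload: malformed line: ", lines[bad][1L])
  vals <- stats::setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
  need <- c(ID_FIELDS, "Code")
  if (!all(need %in% names(vals)))
    stop("parse_id_payload: missing field(s): ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  as.list(vals[need])
}
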