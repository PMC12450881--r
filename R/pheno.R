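# Phenotypic diversity: Shannon-Weaver indices, coefficients of
# variation, descriptive summaries and trait correlations.

#' Shannon-Weaver diversity index
#'
#' `H' = -sum(p * ln p)` in nats, with `0 * ln 0 := 0`. Accepts class
#' frequencies that sum to 1 within `tol` (renormalized) and rejects
#' negative entries.
#'
#' @param p numeric vector of class frequencies.
#' @param tol tolerance on `sum(p) - 1`.
#' @return the diversity index in nats.
#' @export
shannon_weaver <- function(p, tol = 1e-9) {
  p <- as.numeric(p)
  if (anyNA(p)) stop("shannon_weaver: frequencies contain NA")
  if (any(p < 0)) stop("shannon_weaver: negative frequency")
  s <- sum(p)
  if (abs(s - 1) > tol)
    stop("shannon_weaver: frequencies sum to ", format(s), ", not 1")
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Bin a quantitative trait into 10 diversity classes
#'
#' Class boundaries are `mean + k * sd` for `k = -2, -1.5, ..., +2`
#' (first class open below, last open above), the standard 10-class
#' grid of the germplasm-diversity literature. Frequencies are taken
#' over non-missing values.
#'
#' @param x numeric vector with at least 2 distinct non-missing values.
#' @return numeric vector of 10 class frequencies summing to 1.
#' @export
bin_quantitative <- function(x) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2L)
    stop("bin_quantitative: need >= 2 distinct non-missing values (sd = 0)")
  m <- mean(x); s <- stats::sd(x)
  breaks <- c(-Inf, m + seq(-2, 2, by = 0.5) * s, Inf)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE), nbins = 10L)
  counts / length(x)
}

#' Per-trait descriptive and diversity summaries
#'
#' Quantitative traits get mean, sd, range, `CV% = 100 * sd / mean` and a
#' Shannon-Weaver index over the 10-class [bin_quantitative()] grid.
#' Qualitative traits get their class frequencies' Shannon-Weaver index
#' directly; their CV is reported as `NA` (a dispersion ratio over
#' arbitrary class codes is not meaningful).
#'
#' @param traits a [trait_matrix()].
#' @return data frame with one row per trait: `trait`, `kind`, `unit`,
#'   `n`, `mean`, `sd`, `min`, `max`, `cv_percent`, `diversity`.
#' @export
trait_summaries <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  v <- traits$values
  out <- lapply(colnames(v), function(tr) {
    x <- v[, tr]
    x <- x[!is.na(x)]
    if (!length(x)) stop("trait_summaries: trait '", tr, "' is all missing")
    if (traits$kinds[tr] == "quantitative") {
      h <- if (length(unique(x)) >= 2L) shannon_weaver(bin_quantitative(x)) else 0
      data.frame(trait = tr, kind = "quantitative", unit = traits$units[tr],
                 n = length(x), mean = mean(x), sd = stats::sd(x),
                 min = min(x), max = max(x),
                 cv_percent = 100 * stats::sd(x) / mean(x),
                 diversity = h, stringsAsFactors = FALSE)
    } else {
      freq <- as.numeric(table(x)) / length(x)
      data.frame(trait = tr, kind = "qualitative", unit = traits$units[tr],
                 n = length(x), mean = mean(x), sd = stats::sd(x),
                 min = min(x), max = max(x), cv_percent = NA_real_,
                 diversity = shannon_weaver(freq), stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Class frequency table for a qualitative trait
#' @param traits a [trait_matrix()].
#' @param trait name of a qualitative trait.
#' @return data frame of `class` codes and `frequency` over non-missing values.
#' @export
class_frequencies <- function(traits, trait) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (!trait %in% colnames(traits$values)) stop("unknown trait: ", trait)
  x <- traits$values[, trait]
  x <- x[!is.na(x)]
  tab <- table(x)
  data.frame(class = as.numeric(names(tab)),
             frequency = as.numeric(tab) / length(x))
}

#' Pairwise trait correlations with significance
#'
#' Pairwise-complete Pearson (default) or Spearman correlations over all
#' traits; qualitative graded traits enter as their integer class codes.
#' Pairs with fewer than 3 complete observations are flagged `NA`.
#' Two-sided p-values come from [stats::cor.test()].
#'
#' @param traits a [trait_matrix()].
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `trait_correlation` with symmetric matrices `r`
#'   (unit diagonal) and `p`, and `method`.
#' @export
trait_correlations <- function(traits, method = c("pearson", "spearman")) {
  stopifnot(inherits(traits, "trait_matrix"))
  method <- match.arg(method)
  v <- traits$values
  p <- ncol(v)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(v), colnames(v)))
  pv <- r
  diag(r) <- 1; diag(pv) <- 0
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    ok <- !is.na(v[, i]) & !is.na(v[, j])
    if (sum(ok) < 3L) next
    ct <- suppressWarnings(
      stats::cor.test(v[ok, i], v[ok, j], method = method, exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  structure(list(r = r, p = pv, method = method), class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat("trait_correlation (", x$method, "), ", ncol(x$r), " traits\n", sep = "")
  stars <- ifelse(is.na(x$p), "?", ifelse(x$p < 0.01, "**",
                  ifelse(x$p < 0.05, "*", "")))
  m <- matrix(paste0(formatC(x$r, digits = 2, format = "f"), stars),
              ncol(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  cat("* p < 0.05 (significant), ** p < 0.01 (highly significant)\n")
  invisible(x)
}
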