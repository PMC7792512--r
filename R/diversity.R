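#' Species richness of one site
#'
#' Number of species with at least one observed individual.
#'
#' @param counts numeric vector of per-species counts for one site.
#' @return Integer richness.
#' @export
richness <- function(counts) {
  if (!length(counts)) stop("empty count vector", call. = FALSE)
  sum(counts > 0)
}

#' Smith-Wilson Evar evenness of one site
#'
#' Evar = 1 - (2/pi) * arctan(V), where V is the variance of log abundances
#' over the S observed species. The index is 1 for perfectly even abundances
#' and decreases towards 0 as the abundance distribution becomes more
#' skewed; it is invariant to multiplying all abundances by a constant.
#' Species with zero count do not enter (log 0 is undefined).
#'
#' The default uses the population variance (divide by S), the form used in
#' standard community-ecology software; `variant = "sample"` divides by
#' S - 1 instead. A single observed species has zero log-variance and
#' returns 1 under either variant.
#'
#' @param counts numeric vector of per-species counts for one site.
#' @param variant `"population"` (divide by S, default) or `"sample"`
#'   (divide by S - 1).
#' @return Evenness in (0, 1].
#' @examples
#' evar(c(5, 5, 5))      # 1: perfectly even
#' evar(c(1, exp(1)))    # 1 - (2/pi) * atan(0.25)
#' @export
evar <- function(counts, variant = c("population", "sample")) {
  variant <- match.arg(variant)
  n <- counts[counts > 0]
  if (!length(n)) stop("all counts are zero: evenness undefined",
                       call. = FALSE)
  s <- length(n)
  if (s == 1L) return(1)
  ln <- log(n)
  v <- sum((ln - mean(ln))^2) / if (variant == "population") s else s - 1L
  1 - (2 / pi) * atan(v)
}

#' Per-site diversity table
#'
#' One row per site with its habitat label, species richness, Evar evenness
#' and total abundance, ready for the habitat-effect models.
#'
#' @param x an [abundance_matrix()].
#' @param evar_variant passed to [evar()].
#' @return A data frame with columns `site`, `habitat`, `richness`, `evar`,
#'   `abundance`.
#' @export
diversity_table <- function(x, evar_variant = "population") {
  stopifnot(inherits(x, "abundance_matrix"))
  m <- x$counts
  data.frame(
    site = rownames(m),
    habitat = unname(x$habitat),
    richness = apply(m, 1L, richness),
    evar = apply(m, 1L, evar, variant = evar_variant),
    abundance = rowSums(m),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
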