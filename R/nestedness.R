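#' Connectance of a bipartite network
#'
#' Realized proportion of all possible patch-species links:
#' `n_links / (n_patches * n_species)`.
#'
#' @param net a `bipartite_network` (or `abundance_matrix`).
#' @return Value in \[0, 1\].
#' @export
connectance <- function(net) {
  if (inherits(net, "abundance_matrix")) net <- build_bipartite(net)
  stopifnot(inherits(net, "bipartite_network"))
  net$n_links / (nrow(net$counts) * ncol(net$counts))
}

#' Weighted NODF nestedness
#'
#' Quantitative nestedness based on Overlap and Decreasing Fill, on the
#' 0 (non-nested) to 100 (perfectly nested) scale. An ordered pair
#' (upper row i, lower row j) of the sorted matrix contributes
#' `100 * |{k : 0 < w[j,k] < w[i,k]}| / fill_j`, where `fill_j` is the
#' number of nonzero cells of the lower row, provided the pair's ordering
#' key strictly decreases (tied pairs contribute 0). Column pairs are
#' treated symmetrically, and the statistic is the mean contribution over
#' all row pairs and column pairs.
#'
#' Two conventions for the decrease condition are in circulation and can
#' differ appreciably:
#' \describe{
#'   \item{`"fill"` (default)}{rows/columns are sorted and compared by their
#'     number of nonzero cells (binary fill), with weighted totals breaking
#'     ties in the sort only. This is the convention of the standard
#'     community-ecology implementations, so published quantitative NODF
#'     values are normally on this definition.}
#'   \item{`"totals"`}{rows/columns are sorted and compared by their
#'     weighted marginal totals.}
#' }
#'
#' A strictly nested matrix with strictly decreasing rows and columns scores
#' 100 under either convention; a checkerboard with no overlap scores 0.
#'
#' @param net a `bipartite_network`, `abundance_matrix`, or plain numeric
#'   matrix of non-negative weights.
#' @param condition `"fill"` or `"totals"`, see Details.
#' @return Value in \[0, 100\].
#' @references Almeida-Neto M., Ulrich W. (2011) A straightforward
#'   computational approach for measuring nestedness using quantitative
#'   matrices. Environmental Modelling & Software 26, 173-178.
#' @export
weighted_nodf <- function(net, condition = c("fill", "totals")) {
  condition <- match.arg(condition)
  m <- metric_matrix(net)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("weighted NODF needs at least 2 rows and 2 columns", call. = FALSE)
  }
  key <- function(mat) {
    if (condition == "fill") rowSums(mat > 0) else rowSums(mat)
  }
  m <- m[order(key(m), rowSums(m), decreasing = TRUE),
         order(key(t(m)), colSums(m), decreasing = TRUE), drop = FALSE]
  (sum(wnodf_pair_contribs(m, key(m))) +
     sum(wnodf_pair_contribs(t(m), key(t(m))))) /
    (choose(nrow(m), 2) + choose(ncol(m), 2))
}

# Row-pair contributions of a matrix already sorted by decreasing `key`.
# Returns one value per ordered pair (i upper, j lower), vectorized over the
# lower rows for each upper row.
wnodf_pair_contribs <- function(m, key) {
  n <- nrow(m)
  fill <- rowSums(m > 0)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) {
    lower <- (i + 1L):n
    below <- m[lower, , drop = FALSE]
    upper <- matrix(m[i, ], nrow = length(lower), ncol = ncol(m),
                    byrow = TRUE)
    overlap <- rowSums(below > 0 & below < upper)
    contrib <- ifelse(key[lower] < key[i] & fill[lower] > 0,
                      100 * overlap / fill[lower], 0)
    out <- c(out, contrib)
  }
  out
}

# Internal: extract the weight matrix from any accepted input.
metric_matrix <- function(net) {
  if (inherits(net, "abundance_matrix")) return(net$counts)
  if (inherits(net, "bipartite_network")) return(net$counts)
  if (is.matrix(net) && is.numeric(net)) {
    if (any(net < 0)) stop("negative weights are not allowed", call. = FALSE)
    return(net)
  }
  stop("expected a bipartite network, abundance matrix, or numeric matrix",
       call. = FALSE)
}
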