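#' Patefield fixed-margin null model
#'
#' Generates random integer matrices with exactly the observed row and
#' column totals, drawn uniformly over all such tables (Patefield's 1981
#' allocation algorithm, as implemented in [stats::r2dtable()]), and
#' evaluates a network statistic on each replicate. The resulting ensemble
#' calibrates the observed value as a z-score.
#'
#' @param net a `bipartite_network` (or `abundance_matrix`) with integer
#'   weights.
#' @param statistic a function taking a count matrix and returning a single
#'   number (e.g. `weighted_nodf`, or a modularity search wrapped to return
#'   its Q).
#' @param n number of null replicates (the conventional default is 1000).
#' @param seed integer seed; the replicate stream is fully determined by it.
#' @param statistic_name label stored in the ensemble.
#' @return An object of class `"null_ensemble"`: list with `observed`,
#'   `null_values`, `n`, `mean`, `sd` (population sd over replicates),
#'   `z = (observed - mean)/sd` (`NA` and `degenerate = TRUE` when sd is 0),
#'   `statistic` and `seed`.
#' @references Patefield W.M. (1981) An efficient method of generating
#'   random R x C tables with given row and column totals. Applied
#'   Statistics 30, 91-97.
#' @export
patefield_null <- function(net, statistic, n = 1000L, seed = NULL,
                           statistic_name = deparse(substitute(statistic))) {
  if (inherits(net, "abundance_matrix")) net <- build_bipartite(net)
  stopifnot(inherits(net, "bipartite_network"))
  m <- net$counts
  if (!is_count_matrix(m)) {
    stop("Patefield nulls require non-negative integer weights",
         call. = FALSE)
  }
  observed <- statistic(m)
  nulls <- with_seed(seed, {
    reps <- patefield_draws(m, n)
    vapply(reps, statistic, numeric(1))
  })
  new_null_ensemble(observed, nulls, statistic_name, seed)
}

#' Draw Patefield fixed-margin replicates of a count matrix
#'
#' @param m non-negative integer matrix.
#' @param n number of replicates.
#' @return A list of `n` integer matrices, each with the row and column
#'   totals of `m` and its dimnames.
#' @export
patefield_draws <- function(m, n) {
  stopifnot(is_count_matrix(m))
  if (nrow(m) == 1L || ncol(m) == 1L) {
    # margins fully determine the table
    return(rep(list(m), n))
  }
  reps <- stats::r2dtable(n, rowSums(m), colSums(m))
  lapply(reps, function(r) { dimnames(r) <- dimnames(m); r })
}

#' z-score of an observed statistic against a null ensemble
#'
#' @param observed the observed value.
#' @param null_values numeric vector of the statistic over null replicates.
#' @param statistic_name,seed stored as metadata.
#' @return A `null_ensemble` object (see [patefield_null()]).
#' @export
z_score <- function(observed, null_values, statistic_name = "statistic",
                    seed = NULL) {
  new_null_ensemble(observed, null_values, statistic_name, seed)
}

new_null_ensemble <- function(observed, null_values, statistic_name, seed) {
  n <- length(null_values)
  mu <- mean(null_values)
  sigma <- sqrt(mean((null_values - mu)^2))   # population sd
  degenerate <- !is.finite(sigma) || sigma == 0
  structure(list(
    observed = observed,
    null_values = null_values,
    n = n,
    mean = mu,
    sd = sigma,
    z = if (degenerate) NA_real_ else (observed - mu) / sigma,
    degenerate = degenerate,
    statistic = statistic_name,
    seed = seed
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble for %s: %d replicates (seed %s)\n",
              x$statistic, x$n, x$seed %||% "none"))
  cat(sprintf("  observed %.4f, null mean %.4f (sd %.4f)\n",
              x$observed, x$mean, x$sd))
  if (x$degenerate) {
    cat("  degenerate null distribution (sd = 0): no finite z-score\n")
  } else {
    cat(sprintf("  z = %.2f\n", x$z))
  }
  invisible(x)
}
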