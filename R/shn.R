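#' Species-habitat network analysis
#'
#' Runs the full analysis of a site-by-species abundance matrix with habitat
#' labels, in one call:
#'
#' 1. per-site diversity (richness, Evar evenness, abundance);
#' 2. bipartite network architecture: connectance, weighted NODF, Barber
#'    modularity (stochastic optimization, best of `n_restarts`), robustness
#'    to rarest-first species extinctions, and z-scores of weighted NODF and
#'    modularity against `n_nulls` Patefield fixed-margin null models;
#' 3. unipartite patch projection: Opsahl weighted degree centrality at
#'    `alpha`, community detection (multilevel, walktrap, spinglass),
#'    mixing parameter of the multilevel partition, and adjusted Rand
#'    agreement of every partition with the habitat labelling;
#' 4. habitat-effect OLS models for richness, evenness and centrality with
#'    Tukey HSD letters, and Pearson correlations of centrality with
#'    richness and evenness.
#'
#' All stochastic stages derive their own seed from `seed` with fixed
#' per-stage offsets, so results are reproducible end to end and adding a
#' stage never perturbs another stage's stream.
#'
#' @param x an [abundance_matrix()], or a path to a CSV readable by
#'   [read_abundance()].
#' @param n_nulls Patefield null replicates for the z-scores (default 1000).
#' @param alpha centrality tuning parameter (default 0.5).
#' @param seed integer seed for all stochastic stages.
#' @param reference reference habitat for the linear models (default: the
#'   habitat with most sites).
#' @param algorithms community-detection algorithms to run.
#' @param n_restarts restarts for the modularity search on the observed
#'   matrix.
#' @param null_restarts restarts for the modularity search on each null
#'   replicate (fewer, since only the ensemble mean and sd matter).
#' @param evar_variant passed to [evar()].
#' @return An object of class `"shn"`; see Details. Use `print()`,
#'   `summary()`, `plot()` and [write_report()] on it.
#' @details The returned list contains `matrix`, `diversity`, `bipartite`
#'   (with `metrics`, `partition`, `curve`, `nulls`), `unipartite` (with
#'   `network`, `centrality`, `communities`, `mixing`, `agreement`),
#'   `models` (per-response `habitat_lm` fits, `letters`, `correlations`)
#'   and `config`.
#' @examples
#' land <- generate_landscape(seed = 1)
#' fit <- shn(land$matrix, n_nulls = 50, seed = 1)
#' fit
#' @export
shn <- function(x, n_nulls = 1000L, alpha = 0.5, seed = NULL,
                reference = NULL,
                algorithms = c("multilevel", "walktrap", "spinglass"),
                n_restarts = 20L, null_restarts = 4L,
                evar_variant = "population") {
  if (is.character(x)) x <- read_abundance(x)
  stopifnot(inherits(x, "abundance_matrix"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (is.null(reference)) {
    reference <- names(sort(table(x$habitat), decreasing = TRUE))[1L]
  }

  div <- diversity_table(x, evar_variant = evar_variant)
  bip <- build_bipartite(x)

  part <- optimize_modularity(bip, seed = stage_seed(seed, "modularity"),
                              n_restarts = n_restarts,
                              init = list(habitat_init(bip)))
  curve <- robustness(bip)
  q_of <- function(m) {
    optimize_modularity(
      abundance_matrix(m, x$habitat[rownames(m)]),
      seed = NULL, n_restarts = null_restarts)$quality
  }
  nulls <- with_seed(stage_seed(seed, "nulls"), {
    reps <- patefield_draws(bip$counts, n_nulls)
    list(
      wnodf = z_score(weighted_nodf(bip),
                      vapply(reps, weighted_nodf, numeric(1)),
                      "weighted NODF", seed),
      modularity = z_score(part$quality,
                           vapply(reps, q_of, numeric(1)),
                           "Barber modularity", seed)
    )
  })
  metrics <- list(
    connectance = connectance(bip),
    weighted_nodf = nulls$wnodf$observed,
    wnodf_z = nulls$wnodf$z,
    modularity = part$quality,
    modularity_z = nulls$modularity$z,
    robustness = curve$robustness,
    n_nulls = n_nulls
  )

  uni <- project_unipartite(bip)
  cent <- weighted_degree_centrality(uni, alpha = alpha)
  comm_seed <- stage_seed(seed, "communities")
  communities <- lapply(stats::setNames(algorithms, algorithms),
                        function(a) detect_communities(uni, a,
                                                       seed = comm_seed))
  habitat_part <- as_partition(x$habitat, net = uni, algorithm = "habitat")
  agreement <- vapply(communities, partition_agreement, numeric(1),
                      b = habitat_part)
  mixing <- mixing_parameter(
    uni, communities[[if ("multilevel" %in% algorithms) "multilevel" else 1L]])

  site_cent <- stats::setNames(cent$centrality, cent$patch)[div$site]
  models <- list(
    richness = fit_habitat_lm(div$richness, div$habitat, reference,
                              response = "richness"),
    evenness = fit_habitat_lm(div$evar, div$habitat, reference,
                              response = "evenness"),
    centrality = fit_habitat_lm(site_cent, div$habitat, reference,
                                response = "centrality")
  )
  letters_ <- lapply(models, tukey_letters)
  correlations <- list(
    centrality_richness = pearson(site_cent, div$richness),
    centrality_evenness = pearson(site_cent, div$evar)
  )

  structure(list(
    matrix = x,
    diversity = div,
    bipartite = list(network = bip, metrics = metrics, partition = part,
                     curve = curve, nulls = nulls),
    unipartite = list(network = uni, centrality = cent,
                      communities = communities, mixing = mixing,
                      agreement = agreement, habitat_partition = habitat_part),
    models = list(fits = models, letters = letters_,
                  correlations = correlations),
    config = list(n_nulls = n_nulls, alpha = alpha, seed = seed,
                  reference = reference, algorithms = algorithms,
                  n_restarts = n_restarts, null_restarts = null_restarts,
                  evar_variant = evar_variant)
  ), class = "shn")
}

# Habitat labelling as a bipartite starting partition: patches take their
# habitat's module, each species starts in the module where it is most
# abundant.
habitat_init <- function(bip) {
  hm <- as.integer(factor(bip$habitat))
  names(hm) <- rownames(bip$counts)
  agg <- rowsum(bip$counts, hm)
  sp <- as.integer(rownames(agg))[max.col(t(agg), ties.method = "first")]
  names(sp) <- colnames(bip$counts)
  list(patches = hm, species = sp)
}

#' @export
print.shn <- function(x, ...) {
  m <- x$bipartite$metrics
  cat("Species-habitat network analysis\n")
  cat(sprintf("  %d patches x %d species, %d individuals\n",
              nrow(x$matrix$counts), ncol(x$matrix$counts),
              sum(x$matrix$counts)))
  cat(sprintf("  connectance = %.2f, weighted NODF = %.2f (z = %.1f)\n",
              m$connectance, m$weighted_nodf, m$wnodf_z))
  cat(sprintf("  modularity = %.2f (z = %.1f, %d modules), robustness = %.2f\n",
              m$modularity, m$modularity_z,
              x$bipartite$partition$n_communities, m$robustness))
  nc <- vapply(x$unipartite$communities, `[[`, integer(1), "n_communities")
  cat(sprintf("  communities: %s\n",
              paste(sprintf("%s = %d", names(nc), nc), collapse = ", ")))
  cat(sprintf("  centrality (alpha = %.2f): mean %.2f (min = %.2f, max = %.2f)\n",
              x$config$alpha, mean(x$unipartite$centrality$centrality),
              min(x$unipartite$centrality$centrality),
              max(x$unipartite$centrality$centrality)))
  invisible(x)
}

#' @export
summary.shn <- function(object, ...) {
  print(object)
  cat(sprintf("  mixing parameter: mu = %.2f (degree), %.2f (strength)\n",
              object$unipartite$mixing$mu_degree,
              object$unipartite$mixing$mu_strength))
  ag <- object$unipartite$agreement
  cat(sprintf("  agreement with habitat labels (ARI): %s\n",
              paste(sprintf("%s = %.2f", names(ag), ag), collapse = ", ")))
  co <- object$models$correlations
  cat(sprintf("  Pearson r(centrality, richness) = %.2f, r(centrality, evenness) = %.2f\n",
              co$centrality_richness$r, co$centrality_evenness$r))
  cat("\n")
  for (f in object$models$fits) { print(f); cat("\n") }
  invisible(object)
}

#' @export
plot.shn <- function(x, which = c("curve", "diversity"), ...) {
  which <- match.arg(which)
  if (which == "curve") {
    plot(x$bipartite$curve, ...)
  } else {
    op <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(op))
    hab <- factor(x$diversity$habitat)
    graphics::boxplot(x$diversity$richness ~ hab, ylab = "Richness",
                      xlab = "", las = 2)
    graphics::boxplot(x$diversity$evar ~ hab, ylab = "Evenness (Evar)",
                      xlab = "", las = 2)
    cent <- stats::setNames(x$unipartite$centrality$centrality,
                            x$unipartite$centrality$patch)[x$diversity$site]
    graphics::boxplot(cent ~ hab, ylab = "Weighted degree centrality",
                      xlab = "", las = 2)
  }
  invisible(x)
}

#' Write the analysis report bundle
#'
#' Exports an `shn` object to a directory of plain-text artifacts: the
#' headline metrics as JSON (including the effective configuration for
#' provenance), the per-site diversity and centrality tables, the module
#' and community memberships, the extinction curve, and the model
#' coefficient tables. Identical analyses produce byte-identical files.
#'
#' @param x an `shn` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "shn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  m <- x$bipartite$metrics
  report <- list(
    connectance = m$connectance,
    wnodf = m$weighted_nodf,
    wnodf_z = m$wnodf_z,
    modularity = m$modularity,
    modularity_z = m$modularity_z,
    robustness = m$robustness,
    n_modules = x$bipartite$partition$n_communities,
    n_communities = lapply(x$unipartite$communities, `[[`, "n_communities"),
    mixing = list(mu_degree = x$unipartite$mixing$mu_degree,
                  mu_strength = x$unipartite$mixing$mu_strength),
    agreement_ari = as.list(x$unipartite$agreement),
    correlations = lapply(x$models$correlations,
                          function(ct) list(r = ct$r, p = ct$p)),
    config = x$config[c("n_nulls", "alpha", "seed", "reference",
                        "algorithms", "n_restarts", "null_restarts",
                        "evar_variant")]
  )
  jsonlite::write_json(report, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  utils::write.csv(x$diversity, p("diversity.csv"), row.names = FALSE)
  utils::write.csv(x$unipartite$centrality, p("centrality.csv"),
                   row.names = FALSE)
  part <- x$bipartite$partition
  utils::write.csv(data.frame(
    node = c(names(part$patches), names(part$species)),
    mode = rep(c("patch", "species"),
               c(length(part$patches), length(part$species))),
    module = c(unname(part$patches), unname(part$species))
  ), p("modules.csv"), row.names = FALSE)
  memb <- data.frame(patch = names(x$unipartite$habitat_partition$membership))
  for (a in names(x$unipartite$communities)) {
    memb[[a]] <- unname(
      x$unipartite$communities[[a]]$membership[memb$patch])
  }
  utils::write.csv(memb, p("communities.csv"), row.names = FALSE)
  utils::write.csv(data.frame(x = x$bipartite$curve$x,
                              y = x$bipartite$curve$y),
                   p("extinction_curve.csv"), row.names = FALSE)
  for (nm in names(x$models$fits)) {
    utils::write.csv(x$models$fits[[nm]]$coefficients,
                     p(paste0("lm_", nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
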