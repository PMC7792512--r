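#' Specification of a synthetic species-habitat landscape
#'
#' Parameters for [generate_landscape()]. The defaults emulate the shape of
#' a heterogeneous protected-area survey: five habitat types with 10, 10,
#' 10, 7 and 7 sampled patches (44 sites in all), eight specialist species
#' per habitat plus 34 habitat generalists (74 species in all), and skewed
#' log-normal abundances.
#'
#' Each specialist occupies a site of its own habitat with probability
#' `p_in` and a site of any other habitat with probability `p_out`;
#' generalists occupy any site with probability `p_gen`. Occupied cells
#' receive an abundance drawn as `ceiling(rlnorm(mu_ln, sigma_ln))`, so all
#' stored counts are at least 1. The defaults `p_in = 0.6`, `p_out = 0.1`,
#' `p_gen = 0.35` give an expected connectance near 0.28, and the
#' log-normal parameters `mu_ln = 1`, `sigma_ln = 1.2` reproduce the strong
#' abundance skew (site maxima far above the mean) typical of butterfly
#' count data.
#'
#' @param n_habitats number of habitat types.
#' @param sites_per_habitat integer vector (recycled) of patches per
#'   habitat.
#' @param specialists_per_habitat specialist species per habitat.
#' @param n_generalists habitat-generalist species.
#' @param p_in,p_out,p_gen occupancy probabilities (must satisfy
#'   `0 <= p_out <= p_in <= 1`).
#' @param mu_ln,sigma_ln log-normal abundance parameters.
#' @return A list of class `"landscape_spec"`.
#' @export
landscape_spec <- function(n_habitats = 5L,
                           sites_per_habitat = c(10L, 10L, 10L, 7L, 7L),
                           specialists_per_habitat = 8L,
                           n_generalists = 34L,
                           p_in = 0.6, p_out = 0.1, p_gen = 0.35,
                           mu_ln = 1.0, sigma_ln = 1.2) {
  sites_per_habitat <- rep_len(as.integer(sites_per_habitat), n_habitats)
  stopifnot(
    n_habitats >= 1L, all(sites_per_habitat >= 1L),
    specialists_per_habitat >= 0L, n_generalists >= 0L,
    specialists_per_habitat + n_generalists >= 1L,
    p_out >= 0, p_in >= p_out, p_in <= 1, p_gen >= 0, p_gen <= 1,
    sigma_ln >= 0
  )
  structure(list(
    n_habitats = as.integer(n_habitats),
    sites_per_habitat = sites_per_habitat,
    specialists_per_habitat = as.integer(specialists_per_habitat),
    n_generalists = as.integer(n_generalists),
    p_in = p_in, p_out = p_out, p_gen = p_gen,
    mu_ln = mu_ln, sigma_ln = sigma_ln
  ), class = "landscape_spec")
}

#' Generate a synthetic species-habitat abundance matrix
#'
#' Draws a site-by-species count matrix with a planted habitat partition:
#' specialist species concentrate in their own habitat's patches, generalist
#' species spread over the whole landscape, and abundances are skewed
#' (log-normal rounded up). The planted truth (habitat per site, role per
#' species) is returned alongside, so community-recovery and
#' parameter-recovery experiments can score detected structure against it.
#'
#' Sites that end up with no species, or species never placed, are redrawn
#' (and recorded in the truth object) so the result always satisfies the
#' abundance-matrix invariants.
#'
#' @param spec a [landscape_spec()].
#' @param seed integer seed; identical spec + seed give an identical matrix.
#' @return A list with `matrix` (an [abundance_matrix()]) and `truth` (list
#'   with `habitat`, `role` — `"generalist"` or the habitat a specialist
#'   belongs to —, `redrawn_sites`, `redrawn_species` and the `spec`).
#' @export
generate_landscape <- function(spec = landscape_spec(), seed = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  habs <- paste0("habitat", seq_len(spec$n_habitats))
  habitat <- rep(habs, spec$sites_per_habitat)
  n_sites <- length(habitat)
  site_ids <- sprintf("site%02d", seq_len(n_sites))
  role <- c(rep(habs, each = spec$specialists_per_habitat),
            rep("generalist", spec$n_generalists))
  n_sp <- length(role)
  species_ids <- sprintf("sp%02d", seq_len(n_sp))

  p <- matrix(spec$p_gen, n_sites, n_sp)
  for (j in which(role != "generalist")) {
    p[, j] <- ifelse(habitat == role[j], spec$p_in, spec$p_out)
  }
  with_seed(seed, {
    draw <- function() {
      occ <- matrix(stats::runif(n_sites * n_sp), n_sites, n_sp) < p
      counts <- matrix(0L, n_sites, n_sp)
      counts[occ] <- as.integer(ceiling(stats::rlnorm(
        sum(occ), meanlog = spec$mu_ln, sdlog = spec$sigma_ln)))
      counts
    }
    counts <- draw()
    redrawn_sites <- redrawn_species <- character(0)
    for (attempt in seq_len(100L)) {
      empty_r <- rowSums(counts) == 0
      empty_c <- colSums(counts) == 0
      if (!any(empty_r) && !any(empty_c)) break
      redrawn_sites <- union(redrawn_sites, site_ids[empty_r])
      redrawn_species <- union(redrawn_species, species_ids[empty_c])
      fresh <- draw()
      counts[empty_r, ] <- fresh[empty_r, ]
      counts[, empty_c] <- fresh[, empty_c]
    }
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
      stop("could not populate all sites/species; occupancy probabilities ",
           "are too low", call. = FALSE)
    }
    dimnames(counts) <- list(site_ids, species_ids)
    list(
      matrix = abundance_matrix(counts, habitat),
      truth = list(
        habitat = stats::setNames(habitat, site_ids),
        role = stats::setNames(role, species_ids),
        redrawn_sites = redrawn_sites,
        redrawn_species = redrawn_species,
        spec = spec
      )
    )
  })
}

#' Generate a nested abundance matrix
#'
#' Plants nested structure: sites are ranked by capacity, and species
#' `s = 1, 2, ...` occupies the first `ceiling(n_sites * exp(-decay * (s-1)))`
#' ranked sites with weights decreasing down the ranking, so each species'
#' range is a subset of the previous species' range. At `decay = 0` every
#' species fills the whole matrix; larger decay rates give sparser, more
#' strongly nested matrices.
#'
#' @param n_sites,n_species matrix dimensions.
#' @param decay non-negative range-decay rate per species rank.
#' @param habitat optional habitat labels (a single dummy habitat by
#'   default).
#' @return An [abundance_matrix()].
#' @export
generate_nested <- function(n_sites, n_species, decay = 0.2,
                            habitat = NULL) {
  stopifnot(n_sites >= 1L, n_species >= 1L, decay >= 0)
  counts <- matrix(0L, n_sites, n_species)
  for (s in seq_len(n_species)) {
    extent <- ceiling(n_sites * exp(-decay * (s - 1L)))
    extent <- max(1L, min(n_sites, extent))
    # weight falls along the site ranking and with species rank, keeping
    # strictly decreasing rows and columns wherever extents strictly shrink
    counts[seq_len(extent), s] <- (extent - seq_len(extent) + 1L) +
      (n_species - s)
  }
  abundance_matrix(counts,
                   habitat %||% rep("habitat1", n_sites),
                   site_ids = sprintf("site%02d", seq_len(n_sites)),
                   species_ids = sprintf("sp%02d", seq_len(n_species)))
}
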