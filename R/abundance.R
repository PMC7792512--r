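#' Construct a site-by-species abundance matrix with habitat labels
#'
#' The central data container of the package: an integer matrix of individual
#' counts with sites on rows and species on columns, plus one habitat label
#' per site. All downstream analyses (diversity, bipartite and unipartite
#' network metrics, habitat-effect models) start from this object.
#'
#' Counts are individuals pooled over all sampling rounds. Sites with no
#' observed individuals, or species never observed, violate the container's
#' invariants: they are rejected unless `drop_empty = TRUE`, in which case
#' they are dropped with a warning.
#'
#' @param counts integer matrix (or data frame) of non-negative counts,
#'   rows = sites, columns = species. Row and column names are used as site
#'   and species identifiers when `site_ids`/`species_ids` are missing.
#' @param habitat character vector of habitat labels, one per site.
#' @param site_ids,species_ids optional identifier vectors overriding the
#'   dimnames of `counts`.
#' @param drop_empty drop all-zero rows/columns (with a warning) instead of
#'   failing validation.
#' @return An object of class `"abundance_matrix"`: a list with elements
#'   `counts` (named integer matrix) and `habitat` (character vector named by
#'   site).
#' @examples
#' m <- abundance_matrix(rbind(A = c(s1 = 1, s2 = 0), B = c(s1 = 0, s2 = 2)),
#'                       habitat = c("meadow", "grassland"))
#' m
#' @seealso [read_abundance()], [build_bipartite()], [diversity_table()]
#' @export
abundance_matrix <- function(counts, habitat, site_ids = NULL,
                             species_ids = NULL, drop_empty = FALSE) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  site_ids <- as.character(site_ids %||% rownames(counts) %||%
                             paste0("site", seq_len(nrow(counts))))
  species_ids <- as.character(species_ids %||% colnames(counts) %||%
                                paste0("sp", seq_len(ncol(counts))))
  if (length(site_ids) != nrow(counts)) {
    stop("length of `site_ids` does not match the number of rows",
         call. = FALSE)
  }
  if (length(species_ids) != ncol(counts)) {
    stop("length of `species_ids` does not match the number of columns",
         call. = FALSE)
  }
  if (anyDuplicated(site_ids)) {
    stop("duplicate site identifier: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species_ids)) {
    stop("duplicate species identifier: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "counts must be non-negative integers; offending cell: site '%s', species '%s'",
      site_ids[bad[1, 1]], species_ids[bad[1, 2]]), call. = FALSE)
  }
  habitat <- as.character(habitat)
  if (length(habitat) != length(site_ids)) {
    stop("`habitat` must supply exactly one label per site", call. = FALSE)
  }
  if (anyNA(habitat) || any(!nzchar(habitat))) {
    stop("missing habitat label for site: ",
         paste(site_ids[is.na(habitat) | !nzchar(habitat)], collapse = ", "),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(site_ids, species_ids)
  names(habitat) <- site_ids

  empty_sites <- rowSums(counts) == 0
  empty_species <- colSums(counts) == 0
  if (any(empty_sites) || any(empty_species)) {
    msg <- sprintf("%d site(s) and %d species with zero total count",
                   sum(empty_sites), sum(empty_species))
    if (!drop_empty) {
      stop(msg, "; use drop_empty = TRUE to discard them", call. = FALSE)
    }
    warning("dropping ", msg, call. = FALSE)
    counts <- counts[!empty_sites, !empty_species, drop = FALSE]
    habitat <- habitat[!empty_sites]
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("abundance matrix is empty after validation", call. = FALSE)
  }
  structure(list(counts = counts, habitat = habitat),
            class = "abundance_matrix")
}

#' Read an abundance matrix from CSV
#'
#' Reads the flat abundance-table dialect used for species-habitat network
#' data: one row per site, a site-identifier column, a habitat-type column,
#' and one integer count column per species.
#'
#' If every count in the file is 0 or 1 the matrix is presence/absence, not
#' abundance; a warning is issued because the weighted network metrics
#' degenerate on binary data.
#'
#' @param path path to a CSV file.
#' @param site_col,habitat_col names (or 1-based positions) of the site and
#'   habitat columns; all remaining columns are taken as species.
#' @param sep field separator, `","` by default.
#' @param drop_empty passed to [abundance_matrix()].
#' @return An [abundance_matrix()] object.
#' @export
read_abundance <- function(path, site_col = 1L, habitat_col = 2L, sep = ",",
                           drop_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 3L) {
    stop("malformed header: need a site column, a habitat column and at least one species column",
         call. = FALSE)
  }
  idx <- function(col) {
    if (is.numeric(col)) return(as.integer(col))
    i <- match(col, names(df))
    if (is.na(i)) stop("column not found: ", col, call. = FALSE)
    i
  }
  si <- idx(site_col); hi <- idx(habitat_col)
  sites <- as.character(df[[si]])
  habitat <- as.character(df[[hi]])
  sp_cols <- setdiff(seq_along(df), c(si, hi))
  counts <- as.matrix(df[sp_cols])
  if (!is.numeric(counts)) {
    nonnum <- names(df)[sp_cols][!vapply(df[sp_cols], is.numeric, logical(1))]
    stop("non-numeric count column: ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  }
  rownames(counts) <- sites
  mat <- abundance_matrix(counts, habitat, drop_empty = drop_empty)
  if (all(mat$counts %in% c(0L, 1L))) {
    warning("matrix is binary (0/1): weighted metrics degenerate on ",
            "presence/absence data", call. = FALSE)
  }
  mat
}

#' Write an abundance matrix to CSV
#'
#' Emits the same dialect [read_abundance()] reads, so that a write-read
#' round trip reproduces the object exactly.
#'
#' @param x an `abundance_matrix`.
#' @param path output file path.
#' @param site_col,habitat_col column names to use in the header.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, site_col = "site",
                            habitat_col = "habitat") {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(site = rownames(x$counts), habitat = unname(x$habitat),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c(site_col, habitat_col)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "Abundance matrix: %d sites x %d species, %d individuals, %d habitat types\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts),
    length(unique(x$habitat))))
  tab <- table(x$habitat)
  cat("Sites per habitat:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.abundance_matrix <- function(object, ...) {
  ab <- rowSums(object$counts)
  cat(sprintf("%d sites, %d species, %d individuals\n",
              nrow(object$counts), ncol(object$counts), sum(object$counts)))
  cat(sprintf("Per-site abundance: mean %.1f (min = %d, max = %d)\n",
              mean(ab), min(ab), max(ab)))
  cat(sprintf("Per-site richness: mean %.1f (min = %d, max = %d)\n",
              mean(rowSums(object$counts > 0)),
              min(rowSums(object$counts > 0)),
              max(rowSums(object$counts > 0))))
  invisible(object)
}
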