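#' Habitat-effect linear model
#'
#' Ordinary least squares of a per-site response (richness, evenness,
#' centrality, ...) on habitat type with treatment (dummy) coding against a
#' chosen reference habitat. Each coefficient is the difference between a
#' habitat's mean and the reference mean; the intercept is the reference
#' mean. Coefficients carry two-sided t-tests.
#'
#' @param values numeric response, one value per site.
#' @param habitat habitat label per site.
#' @param reference reference habitat level; default is the habitat with the
#'   most sites.
#' @param response name of the response, for printing.
#' @return An object of class `"habitat_lm"`: list with `fit` (the
#'   underlying [stats::lm()] fit), `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `reference`, `response` and
#'   `df_residual`.
#' @export
fit_habitat_lm <- function(values, habitat, reference = NULL,
                           response = deparse(substitute(values))) {
  habitat <- as.character(habitat)
  if (length(values) != length(habitat)) {
    stop("`values` and `habitat` must have the same length", call. = FALSE)
  }
  levels_ <- unique(habitat)
  if (length(levels_) < 2L) {
    stop("need at least two habitat levels", call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- names(sort(table(habitat), decreasing = TRUE))[1L]
  }
  if (!reference %in% levels_) {
    stop("unknown reference level: ", reference, call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("constant response: degenerate fit", call. = FALSE)
  }
  hab <- stats::relevel(factor(habitat), ref = reference)
  fit <- stats::lm(values ~ hab, data = data.frame(values = values,
                                                   hab = hab))
  ct <- summary(fit)$coefficients
  terms_ <- sub("^hab", "", rownames(ct))
  terms_[1L] <- paste0("Intercept (", reference, ")")
  structure(list(
    fit = fit,
    coefficients = data.frame(
      term = terms_,
      estimate = ct[, "Estimate"],
      se = ct[, "Std. Error"],
      t = ct[, "t value"],
      p = ct[, "Pr(>|t|)"],
      row.names = NULL,
      stringsAsFactors = FALSE
    ),
    reference = reference,
    response = response,
    df_residual = fit$df.residual
  ), class = "habitat_lm")
}

#' @export
print.habitat_lm <- function(x, ...) {
  cat(sprintf("Habitat effect on %s (reference: %s)\n", x$response,
              x$reference))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 2)
  tab$se <- round(tab$se, 2)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.habitat_lm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Compact letter display from Tukey's HSD
#'
#' All-pairs comparison of habitat means by Tukey's honestly significant
#' difference test on the studentized range (via [stats::TukeyHSD()] on the
#' model's ANOVA), summarized as letters by the insert-absorb algorithm:
#' habitats sharing no letter differ significantly at `level`.
#'
#' @param fit a `habitat_lm` from [fit_habitat_lm()].
#' @param level significance level (default 0.05).
#' @return A named character vector of letter codes, one per habitat, in
#'   decreasing order of group mean.
#' @export
tukey_letters <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "habitat_lm"))
  mf <- stats::model.frame(fit$fit)
  if (nlevels(mf$hab) < 2L) stop("need at least two groups", call. = FALSE)
  aovfit <- stats::aov(values ~ hab, data = mf)
  tk <- stats::TukeyHSD(aovfit, conf.level = 1 - level)$hab
  groups <- levels(mf$hab)
  means <- tapply(mf$values, mf$hab, mean)
  # significance matrix from the pairwise adjusted p-values
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pair)) {
    # group labels may themselves contain "-": split on the last viable cut
    lab <- rownames(tk)[i]
    found <- FALSE
    for (g1 in groups) {
      g2 <- sub(paste0("^", g1, "-"), "", lab)
      if (startsWith(lab, paste0(g1, "-")) && g2 %in% groups) {
        sig[g1, g2] <- sig[g2, g1] <- tk[i, "p adj"] < level
        found <- TRUE
        break
      }
    }
    if (!found) stop("cannot parse comparison label: ", lab, call. = FALSE)
  }
  letters_insert_absorb(sig, order(-means))
}

# Insert-absorb compact letter display: start from one letter containing all
# groups; for every significantly different pair sharing a letter, duplicate
# the letter column splitting the pair; absorb columns contained in others.
letters_insert_absorb <- function(sig, ord) {
  groups <- rownames(sig)[ord]
  sig <- sig[ord, ord, drop = FALSE]
  n <- length(groups)
  cols <- list(rep(TRUE, n))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      if (cols[[ci]][i] && cols[[ci]][j]) {
        a <- cols[[ci]]; a[j] <- FALSE
        b <- cols[[ci]]; b[i] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb duplicated / contained columns
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] | !cols[[cj]]) && !identical(cols[[ci]], cols[[cj]])) {
        keep[cj] <- FALSE       # cj contained in ci
      }
    }
    dup <- duplicated(vapply(cols, paste, character(1), collapse = ""))
    cols <- cols[keep & !dup]
  }
  lab <- vapply(seq_len(n), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(lab, groups)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return A list with `r` (sample correlation), `p` (two-sided p-value),
#'   and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
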