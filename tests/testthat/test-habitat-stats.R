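test_that("coefficients reproduce the group means exactly", {
  vals <- c(0, 0, 1, 1)
  hab <- c("g1", "g1", "g2", "g2")
  # zero residual variance: the exact fit itself is the point here
  fit <- suppressWarnings(fit_habitat_lm(vals, hab, reference = "g1"))
  expect_equal(unname(coef(fit)), c(0, 1))

  set.seed(61)
  vals <- rnorm(30)
  hab <- sample(c("a", "b", "c"), 30, replace = TRUE)
  fit <- fit_habitat_lm(vals, hab, reference = "b")
  means <- tapply(vals, hab, mean)
  co <- coef(fit)
  expect_equal(unname(co[1]), unname(means["b"]))
  expect_equal(unname(co[1] + co["a"]), unname(means["a"]))
  expect_equal(unname(co[1] + co["c"]), unname(means["c"]))
  # t = estimate / SE on every term
  expect_equal(fit$coefficients$t,
               fit$coefficients$estimate / fit$coefficients$se)
})

test_that("changing the reference moves coefficients but not the fit", {
  set.seed(62)
  vals <- rnorm(24)
  hab <- rep(c("a", "b", "c"), each = 8)
  f1 <- fit_habitat_lm(vals, hab, reference = "a")
  f2 <- fit_habitat_lm(vals, hab, reference = "c")
  expect_equal(unname(fitted(f1$fit)), unname(fitted(f2$fit)))
  expect_equal(sum(residuals(f1$fit)^2), sum(residuals(f2$fit)^2))
  expect_false(isTRUE(all.equal(coef(f1), coef(f2),
                                check.attributes = FALSE)))
})

test_that("degenerate fits are refused", {
  expect_error(fit_habitat_lm(rep(1, 4), c("a", "a", "b", "b")), "constant")
  expect_error(fit_habitat_lm(rnorm(4), rep("a", 4)), "two habitat levels")
  expect_error(fit_habitat_lm(rnorm(4), c("a", "a", "b", "b"),
                              reference = "zz"), "unknown reference")
})

test_that("Tukey letters separate distant groups and merge identical ones", {
  set.seed(63)
  vals <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  hab <- rep(c("low", "high"), each = 5)
  lt <- tukey_letters(fit_habitat_lm(vals, hab, reference = "low"))
  expect_identical(unname(sort(lt)), c("a", "b"))

  # verify against the studentized-range p-value computed directly
  fitlm <- stats::lm(vals ~ hab)
  mse <- sum(residuals(fitlm)^2) / fitlm$df.residual
  qstat <- abs(diff(tapply(vals, hab, mean))) / sqrt(mse / 5)
  p_direct <- stats::ptukey(qstat, nmeans = 2, df = fitlm$df.residual,
                            lower.tail = FALSE)
  expect_lt(p_direct, 0.05)

  vals2 <- rep(c(1.0, 1.1, 0.9, 1.0, 1.05), 3)
  hab2 <- rep(c("x", "y", "z"), each = 5)
  lt2 <- tukey_letters(fit_habitat_lm(vals2, hab2, reference = "x"))
  expect_true(all(lt2 == lt2[1]))
})

test_that("letters form three tiers for three well-separated groups", {
  set.seed(64)
  vals <- c(rnorm(6, 0, 0.2), rnorm(6, 5, 0.2), rnorm(6, 10, 0.2))
  hab <- rep(c("a", "b", "c"), each = 6)
  lt <- tukey_letters(fit_habitat_lm(vals, hab, reference = "a"))
  expect_identical(length(unique(lt)), 3L)
})

test_that("pearson wraps the correlation test faithfully", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x)$r, 1)
  set.seed(65)
  a <- rnorm(20); b <- rnorm(20)
  p1 <- pearson(a, b)
  p2 <- pearson(b, a)
  expect_equal(p1$r, p2$r)
  expect_equal(p1$p, p2$p)
  ref <- stats::cor.test(a, b)
  expect_equal(p1$r, unname(ref$estimate))
  expect_equal(p1$p, ref$p.value)
  # affine invariance up to sign
  expect_equal(pearson(3 * a - 1, b)$r, p1$r)
  expect_equal(pearson(-a, b)$r, -p1$r)
  expect_error(pearson(a, rep(1, 20)), "constant")
  expect_error(pearson(a, b[1:10]), "unequal")
  expect_error(pearson(1:2, 2:3), "at least 3")
})
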