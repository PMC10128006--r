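test_that("exact data is reproduced with zero residual", {
  m <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), FALSE)
  S <- stoich_matrix(m)
  xstar <- c(0.3, 0.7, 0.1, 0, 0)
  y <- as.vector(S %*% xstar)
  names(y) <- rownames(S)
  fit <- fit_extents(m, y)
  expect_lt(fit$residual_norm, 1e-9)
  expect_equal(fit$predicted, y, tolerance = 1e-9)
  expect_true(all(fit$extents >= 0))
})

test_that("the solver matches the brute-force grid oracle on small models", {
  # identifiable two-reaction model, truth on the 0.001 grid
  m2 <- toy2_model()
  S2 <- stoich_matrix(m2)
  w2 <- default_weights(m2)
  xstar <- c(rc_lactate = 0.3, rc_acetogenesis = 0.7)
  y <- as.vector(S2 %*% xstar)
  names(y) <- rownames(S2)
  fit <- fit_extents(m2, y)
  expect_equal(fit$extents, xstar, tolerance = 1e-8)
  oracle <- grid_nnls(S2, y, w2, upper = c(1.2, 1.2))
  expect_equal(oracle$objective, 0, tolerance = 1e-12)
  expect_equal(unname(oracle$argmin), unname(xstar), tolerance = 1e-9)

  # noisy data: continuous optimum must not be beaten by the grid, and the
  # grid minimum must be within grid resolution of it
  set.seed(7)
  for (i in 1:5) {
    yn <- y + stats::rnorm(length(y), 0, 0.05) * (w2 > 0)
    fitn <- fit_extents(m2, yn)
    oracle <- grid_nnls(S2, yn, w2, upper = c(1.3, 1.3))
    expect_lte(fit_rss(fitn), oracle$objective + 1e-9)
    expect_lt(oracle$objective - fit_rss(fitn), 1e-3)
    expect_equal(fitn$extents, oracle$argmin, tolerance = 2e-3,
                 ignore_attr = TRUE)
  }

  # three-reaction model
  m3 <- toy3_model()
  S3 <- stoich_matrix(m3)
  w3 <- default_weights(m3)
  x3 <- c(0.05, 0.12, 0.08)
  y3 <- as.vector(S3 %*% x3)
  names(y3) <- rownames(S3)
  y3n <- y3 + c(0.01, -0.02, 0.015, -0.01, 0.02, 0, 0, 0)
  fit3 <- fit_extents(m3, y3n)
  oracle3 <- grid_nnls(S3, y3n, w3, upper = c(0.2, 0.2, 0.2))
  expect_lte(fit_rss(fit3), oracle3$objective + 1e-9)
  expect_lt(oracle3$objective - fit_rss(fit3), 1e-3)
})

test_that("the quad-culture endpoint fit is tight in both conditions", {
  ctrl <- quad_fit("control")
  expect_gt(ctrl$fit$r_squared, 0.9)
  rmse <- goodness_of_fit(ctrl$fit)$rmse
  expect_lt(abs(ctrl$fit$predicted[["ch4"]] - 1.37), 2 * rmse)
  sulf <- quad_fit("sulfate")
  expect_gt(sulf$fit$r_squared, 0.9)
  expect_true(all(ctrl$fit$extents >= 0) && all(sulf$fit$extents >= 0))
})

test_that("goodness-of-fit statistics follow their definitions", {
  m <- toy2_model()
  S <- stoich_matrix(m)
  y <- as.vector(S %*% c(0.4, 0.6))
  names(y) <- rownames(S)
  perfect <- fit_extents(m, y)
  g <- goodness_of_fit(perfect)
  expect_equal(g$r_squared, 1)
  expect_equal(g$nrmse, 0)

  # a predictor pinned at the observed mean has R^2 = 0 by definition
  fake <- perfect
  w <- fake$weights > 0
  fake$predicted[w] <- mean(fake$observed[w])
  expect_equal(goodness_of_fit(fake)$r_squared, 0, tolerance = 1e-12)

  # normalization conventions differ only in the denominator
  fit <- quad_fit("control")$fit
  yf <- fit$observed[fit$weights > 0]
  g1 <- goodness_of_fit(fit, "mean_abs")
  g2 <- goodness_of_fit(fit, "range")
  g3 <- goodness_of_fit(fit, "sd")
  expect_equal(g1$nrmse * mean(abs(yf)), g1$rmse)
  expect_equal(g2$nrmse * diff(range(yf)), g2$rmse)
  expect_equal(g3$nrmse * stats::sd(yf), g3$rmse)

  few <- fit
  few$weights <- c(1, rep(0, 7))
  expect_error(goodness_of_fit(few), "fewer than 2")
})

test_that("fitting is scale-equivariant and monotone in the reaction set", {
  ctrl <- quad_fit("control")
  for (cc in c(0.5, 3)) {
    scaled <- fit_extents(ctrl$model, cc * ctrl$y)
    expect_equal(scaled$extents, cc * ctrl$fit$extents, tolerance = 1e-6)
    expect_equal(scaled$r_squared, ctrl$fit$r_squared, tolerance = 1e-9)
    expect_equal(scaled$nrmse, ctrl$fit$nrmse, tolerance = 1e-9)
  }
  # removing any reaction (column) can only worsen the best residual
  for (id in names(ctrl$model$reactions)) {
    sub <- fit_extents(ctrl$model, ctrl$y, excluded = id)
    expect_gte(sub$residual_norm + 1e-12, ctrl$fit$residual_norm)
    expect_equal(unname(sub$extents[id]), 0)
  }
})

test_that("fitted predictions conserve carbon and electrons", {
  for (cond in c("control", "sulfate")) {
    qf <- quad_fit(cond)
    tot <- elemental_totals(qf$fit$predicted)
    expect_equal(unname(tot), c(0, 0), tolerance = 1e-9)
  }
})

test_that("fit input validation catches misuse", {
  ctrl <- quad_fit("control")
  expect_error(fit_extents(ctrl$model, ctrl$y[1:3]), "length")
  expect_error(fit_extents(ctrl$model, ctrl$y, weights = rep(0, 8)),
               "all-zero")
  expect_error(fit_extents(ctrl$model, ctrl$y, excluded = "nope"),
               "unknown reaction")
})

test_that("the exclusion scan separates identifiable from redundant models", {
  # identifiable toy with exact data: no alternative survives
  m2 <- toy2_model()
  S2 <- stoich_matrix(m2)
  y <- as.vector(S2 %*% c(0.3, 0.7))
  names(y) <- rownames(S2)
  scan <- exclusion_scan(m2, y, tolerance = 0.05)
  expect_equal(scan$n_distributions, 1L)
  expect_equal(scan$ranges$min, scan$ranges$max, tolerance = 1e-6)

  # the fermenter's two routes are redundant against lactate oxidation:
  # the control community admits more than one equal-fit distribution
  ctrl <- quad_fit("control")
  scan_c <- exclusion_scan(ctrl$model, ctrl$y)
  expect_gt(scan_c$n_distributions, 1L)
  expect_true(all(scan_c$ranges$min <= scan_c$ranges$max))
  nr <- vapply(scan_c$equal_fit, `[[`, 0, "nrmse")
  expect_true(all(scan_c$best$nrmse <= nr + 1e-12))
  # ranges bracket every equal-fit member
  for (f in scan_c$equal_fit) {
    expect_true(all(f$extents >= scan_c$ranges$min - 1e-9))
    expect_true(all(f$extents <= scan_c$ranges$max + 1e-9))
  }
})

test_that("flux ranges collapse for identifiable fluxes and open for degenerate ones", {
  m2 <- toy2_model()
  S2 <- stoich_matrix(m2)
  y <- as.vector(S2 %*% c(0.3, 0.7))
  names(y) <- rownames(S2)
  for (id in colnames(S2)) {
    rg <- flux_range(m2, y, id, slack = 0)
    expect_equal(unname(rg["min"]), unname(rg["max"]), tolerance = 1e-4)
  }

  # duplicated columns with total extent c: each extent ranges over [0, c]
  md <- duplicated_model()
  Sd <- stoich_matrix(md)
  yd <- as.vector(Sd %*% c(0.6, 0.4))
  names(yd) <- rownames(Sd)
  for (id in colnames(Sd)) {
    rg <- flux_range(md, yd, id, slack = 0)
    expect_equal(unname(rg["min"]), 0, tolerance = 1e-4)
    expect_equal(unname(rg["max"]), 1.0, tolerance = 1e-3)
  }

  expect_error(flux_range(m2, y, "rc_lactate", slack = -0.1), "slack")
  expect_error(flux_range(m2, y, "not_a_reaction"), "active reaction")
})

test_that("derived species-level flux ranges match hand-computed degeneracy", {
  # under sulfate the Dv hydrogen-oxidation extent trades off against the
  # lactate routes; its H2 consumption spans from zero up past the best fit
  sulf <- quad_fit("sulfate")
  rg <- species_flux_range(sulf$model, sulf$y, "Dv", "h2", "consumption",
                           slack = 0.05)
  best_cons <- 4 * sulf$fit$extents[["dv_h2_sulfate"]]
  expect_equal(unname(rg[["min"]]), 0, tolerance = 1e-3)
  expect_gte(rg[["max"]] + 1e-6, best_cons)
  # a species without a consuming reaction has an identically zero flux
  ctrl <- quad_fit("control")
  rg0 <- species_flux_range(ctrl$model, ctrl$y, "Dv", "h2", "consumption")
  expect_equal(unname(rg0), c(0, 0))
})
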