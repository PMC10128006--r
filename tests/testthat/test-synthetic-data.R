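test_that("the generator is exact at zero noise and honors its seed", {
  cfg <- generator_config(noise = 0, replicates = 3, seed = 5)
  reps <- generate_endpoint(cfg)
  truth <- attr(reps, "truth")
  m <- cfg$model
  for (o in reps) {
    expect_equal(net_change_vector(o, m), truth, tolerance = 1e-9)
  }
  cfgn <- generator_config(noise = 0.02, replicates = 2, seed = 9)
  a <- generate_endpoint(cfgn)
  b <- generate_endpoint(cfgn)
  expect_equal(net_change_vector(a[[1]], m), net_change_vector(b[[1]], m))
  cfgn2 <- cfgn
  cfgn2$seed <- 10L
  c2 <- generate_endpoint(cfgn2)
  expect_false(isTRUE(all.equal(net_change_vector(a[[1]], m),
                                net_change_vector(c2[[1]], m))))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_endpoint(cfgn)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("generated sulfide sums both sulfidogenic routes", {
  cfg <- generator_config(
    sulfate_present = TRUE,
    extents = c(rc_lactate = 0.5, rc_acetogenesis = 0.8,
                dv_lactate_sulfate = 0.2, dv_h2_sulfate = 0.7725,
                mc_methanogenesis = 0.9),
    noise = 0, replicates = 1, seed = 1)
  o <- generate_endpoint(cfg)[[1]]
  expect_equal(o$net_change[["h2s"]], 0.7725 + 0.2)
})

test_that("noised accumulations are floored at zero and counted", {
  cfg <- generator_config(extents = c(rc_lactate = 0.001),
                          noise = 0.05, replicates = 1, seed = 3)
  o <- generate_endpoint(cfg)[[1]]
  expect_true(all(o$net_change[c("ch4", "h2", "acetate", "lactate")] >= 0))
  expect_true(o$cellulose_mg >= 0)
  expect_true(is.numeric(attr(o, "floored")))
})

test_that("daily-cumulative trajectories are consistent with the endpoint", {
  sched <- matrix(1 / 7, nrow = 5, ncol = 7,
                  dimnames = list(names(generator_config()$extents), NULL))
  cfg <- generator_config(noise = 0, replicates = 1, seed = 2,
                          schedule = sched)
  ts <- generate_timeseries(cfg)
  truth <- attr(generate_endpoint(cfg), "truth")
  day7 <- ts[ts$day == 7, ]
  expect_equal(stats::setNames(day7$cumulative_mmol, day7$metabolite),
               truth, tolerance = 1e-9)
  # noiseless cumulative product curves are non-decreasing
  for (met in c("ch4", "co2")) {
    traj <- ts$cumulative_mmol[ts$metabolite == met][order(ts$day[ts$metabolite == met])]
    expect_true(all(diff(traj) >= -1e-12))
  }

  # all turnover on day 7: flat then jump
  late <- matrix(0, nrow = 5, ncol = 7, dimnames = dimnames(sched))
  late[, 7] <- 1
  cfg_late <- generator_config(noise = 0, replicates = 1, seed = 2,
                               schedule = late)
  ts_late <- generate_timeseries(cfg_late)
  ch4 <- ts_late[ts_late$metabolite == "ch4", ]
  expect_true(all(ch4$cumulative_mmol[ch4$day <= 6] == 0))
  expect_gt(ch4$cumulative_mmol[ch4$day == 7], 0)

  expect_error(generate_timeseries(generator_config(noise = 0)),
               "schedule")
})

test_that("a lagged acetoclastic schedule lets acetate rise then fall", {
  ids <- names(generator_config()$extents)
  sched <- matrix(1 / 7, nrow = 5, ncol = 7, dimnames = list(ids, NULL))
  # acetate consumption concentrated in the last two days
  sched["mc_methanogenesis", ] <- c(0, 0, 0, 0, 0, 0.5, 0.5)
  cfg <- generator_config(noise = 0, replicates = 1, seed = 4,
                          schedule = sched)
  ts <- generate_timeseries(cfg)
  ac <- ts[ts$metabolite == "acetate", ]
  ac <- ac$cumulative_mmol[order(ac$day)]
  expect_gt(max(ac), ac[7])        # rises above its endpoint
  expect_lt(ac[7] - max(ac), 0)    # then declines
})

test_that("schedule validation enforces the simplex constraint", {
  bad <- matrix(1, nrow = 5, ncol = 7,
                dimnames = list(names(generator_config()$extents), NULL))
  expect_error(generator_config(schedule = bad), "sum to 1")
  expect_error(generator_config(extents = c(bogus = 1)), "inactive reaction")
  expect_error(generator_config(noise = -1), "noise")
})

test_that("zero-noise recovery is exact and degeneracy moves to the sum", {
  cfg <- generator_config(noise = 0, replicates = 1, seed = 6)
  rec <- recovery_experiment(cfg, n_runs = 3)
  expect_equal(rec$bias, rep(0, nrow(rec)), tolerance = 1e-8)
  expect_equal(rec$rmse, rep(0, nrow(rec)), tolerance = 1e-8)

  # duplicated columns: the individual extents are not recoverable but the
  # fitted total matches the true total within the noise scale
  md <- duplicated_model()
  Sd <- stoich_matrix(md)
  xt <- c(copy_a = 0.6, copy_b = 0.4)
  set.seed(31)
  sums <- replicate(30, {
    y <- as.vector(Sd %*% xt) + stats::rnorm(8, 0, 0.02) * default_weights(md)
    names(y) <- rownames(Sd)
    sum(fit_extents(md, y)$extents)
  })
  expect_lt(abs(mean(sums) - 1.0), 0.02)
  yd <- stats::setNames(as.vector(Sd %*% xt), rownames(Sd))
  rg <- flux_range(md, yd, "copy_a", slack = 0)
  expect_equal(unname(rg), c(0, 1), tolerance = 1e-3)
})

test_that("refits of simulated quad communities reproduce the generating observables", {
  cfg <- generator_config(noise = 0.02, replicates = 3, seed = 17)
  m <- cfg$model
  truth <- stats::setNames(as.vector(stoich_matrix(m) %*% cfg$extents),
                           m$metabolite_order)
  fitted_w <- default_weights(m) > 0
  se_mean <- 0.02 / sqrt(cfg$replicates)
  hits <- 0L; total <- 0L
  for (run in 1:20) {
    c2 <- cfg; c2$seed <- cfg$seed + run
    reps <- generate_endpoint(c2)
    ys <- vapply(reps, function(o) net_change_vector(o, m),
                 numeric(length(m$metabolite_order)))
    fit <- fit_extents(m, rowMeans(ys))
    dev <- abs(fit$predicted - truth)[fitted_w]
    hits <- hits + sum(dev <= 3 * se_mean)
    total <- total + length(dev)
  }
  expect_gte(hits / total, 0.95)
})
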