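test_that("cellulose mass converts to glucose equivalents", {
  expect_equal(glucose_from_cellulose(162.14), 1)
  expect_equal(glucose_from_cellulose(0), 0)
  expect_equal(glucose_from_cellulose(210.02), 1.295, tolerance = 5e-4)
  expect_equal(glucose_from_cellulose(180.16, monomer_mass = 180.16), 1)
  expect_error(glucose_from_cellulose(-1), "non-negative")
})

test_that("headspace amounts follow the ideal gas law", {
  expect_equal(headspace_moles(101.325, 0.140, 307.15, 1.0), 5.555,
               tolerance = 2e-4)
  expect_equal(headspace_moles(101.325, 0.140, 307.15, 0), 0)
  expect_equal(headspace_moles(2 * 101.325, 0.140, 307.15, 0.5),
               headspace_moles(101.325, 0.140, 307.15, 1.0))
  expect_error(headspace_moles(101.325, 0.140, 307.15, 1.2), "mole_fraction")
  expect_error(headspace_moles(-1, 0.140, 307.15, 0.5), "positive")
})

test_that("the bundled endpoint table parses with the published values", {
  obs <- table1_obs()
  expect_length(obs, 13L)
  quad <- obs[["quad"]]
  expect_equal(quad$net_change[["ch4"]], 1.37)
  expect_equal(quad$cellulose_mg, 210.02)
  expect_equal(quad$uncertainty[["ch4"]], 0.03)
  mono <- obs[["Rc"]]
  expect_equal(mono$net_change[["h2"]], 1.36)
  expect_equal(mono$net_change[["acetate"]], 0.78)
  expect_identical(mono$species_present, "Rc")
  # sugars are converted from umol to mmol on read
  expect_equal(quad$net_change[["glucose"]], 1.66e-3)
  # species flags encoded in the culture labels match the parsed sets
  for (o in obs) {
    expected <- if (startsWith(o$culture_id, "quad")) c("Rc", "Mh", "Mc", "Dv")
      else intersect(strsplit(o$culture_id, "_")[[1]],
                     c("Rc", "Mh", "Mc", "Dv"))
    expect_setequal(o$species_present, expected)
    expect_identical(o$sulfate_added, grepl("_S$", o$culture_id))
  }
  # sulfate-amended Dv cultures carry the inferred sulfide accumulation
  expect_equal(obs[["quad_S"]]$net_change[["h2s"]], 1.17)
  expect_equal(obs[["Rc_Dv_S"]]$net_change[["h2s"]], 1.17)
})

test_that("malformed observation files raise descriptive errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines("culture_id,Rc,Mh,Mc,Dv,sulfate,replicate", empty)
  expect_error(load_observations(empty), "no rows|missing required")
  on.exit(unlink(empty), add = TRUE)

  df <- utils::read.csv(synflux_table1(), check.names = FALSE)
  broken <- tempfile(fileext = ".csv")
  on.exit(unlink(broken), add = TRUE)
  utils::write.csv(df[, setdiff(names(df), "ch4_mmol")], broken,
                   row.names = FALSE)
  expect_error(load_observations(broken), "ch4_mmol")

  df2 <- df
  df2$h2_mmol[3] <- "oops"
  utils::write.csv(df2, broken, row.names = FALSE)
  expect_error(load_observations(broken), "h2_mmol.*row.*3")

  df3 <- df
  df3$Dv[2] <- "maybe"
  utils::write.csv(df3, broken, row.names = FALSE)
  expect_error(load_observations(broken), "Dv.*row.*2")
})

test_that("observations round-trip through the CSV dialect at full precision", {
  obs <- table1_obs()
  # perturb to non-representable decimals to exercise precision
  obs[[1]]$net_change[["acetate"]] <- 1 / 3
  obs[[1]]$cellulose_mg <- 184.39000001
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- load_observations(path)
  expect_identical(names(back), names(obs))
  for (id in names(obs)) {
    expect_equal(back[[id]]$net_change, obs[[id]]$net_change, tolerance = 1e-12)
    expect_equal(back[[id]]$cellulose_mg, obs[[id]]$cellulose_mg,
                 tolerance = 1e-12)
    expect_identical(back[[id]]$species_present, obs[[id]]$species_present)
    expect_equal(back[[id]]$uncertainty[sort(names(back[[id]]$uncertainty))],
                 obs[[id]]$uncertainty[sort(names(obs[[id]]$uncertainty))],
                 tolerance = 1e-12)
  }
})

test_that("net-change vectors are aligned, signed, and flag-complete", {
  m <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), FALSE)
  quad <- table1_obs()[["quad"]]
  y <- net_change_vector(quad, m)
  expect_identical(names(y), model_metabolite_order())
  expect_equal(unname(y["glucose"]), -210.02 / 162.14 + 0.00166,
               tolerance = 1e-12)
  expect_equal(unname(y["glucose"]), -1.293, tolerance = 5e-4)
  expect_equal(unname(y["ch4"]), 1.37)

  ms <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), TRUE)
  ys <- net_change_vector(table1_obs()[["quad_S"]], ms)
  expect_equal(unname(ys["h2s"]), 1.17)
  expect_equal(unname(ys["sulfate"]), -1.17)

  zero <- culture_observation("blank", "Rc", FALSE, "mean", 0,
                              net_change = c(ch4 = 0, co2 = 0, h2 = 0,
                                             h2s = 0, acetate = 0,
                                             lactate = 0, glucose = 0,
                                             cellobiose = 0))
  expect_true(all(net_change_vector(zero, m) == 0))

  incomplete <- culture_observation("partial", "Rc", FALSE, "mean", 10,
                                    net_change = c(ch4 = 0.1, co2 = 0.2))
  expect_error(net_change_vector(incomplete, m), "lactate")
})

test_that("physically impossible observations are rejected", {
  expect_error(
    culture_observation("neg", "Rc", FALSE, "mean", -5,
                        net_change = c(ch4 = 0)),
    "cellulose")
  expect_error(
    culture_observation("neg", "Rc", FALSE, "mean", 5,
                        net_change = c(ch4 = -0.2)),
    "ch4")
})
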