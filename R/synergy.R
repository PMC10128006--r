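#' Phenotype increment of one culture over a baseline
#'
#' Difference of a community phenotype (methane produced, cellulose
#' degraded, ...) between a culture and a reference composition, with the
#' uncertainty propagated as the root-sum-square of the two standard errors
#' (independent cultures).
#'
#' @param culture_value,baseline_value phenotype values (same units).
#' @param culture_se,baseline_se standard errors (default 0).
#' @param units unit label carried through for consistency checks.
#' @param baseline_units unit label of the baseline (must match `units`).
#' @return List with `difference`, `se` and `units`.
#' @examples
#' increment(210.02, 184.39, 2.10, 0.54, units = "mg")
#' @export
increment <- function(culture_value, baseline_value, culture_se = 0,
                      baseline_se = 0, units = "mmol",
                      baseline_units = units) {
  if (!identical(units, baseline_units)) {
    stop("unit mismatch: '", units, "' vs '", baseline_units, "'")
  }
  list(difference = culture_value - baseline_value,
       se = sqrt(culture_se^2 + baseline_se^2),
       units = units)
}

#' Additive (null) expectation of a community phenotype
#'
#' Two additive schemes are used for higher-order (tertiary) interaction
#' analysis and they are not interchangeable:
#' * `"sum_of_values"` - the expectation is the plain sum of the subset
#'   communities' phenotype values (used for methane: quad-culture CH4
#'   versus the sum of the two Dv-containing tri-cultures).
#' * `"sum_of_increments"` - the expectation is the baseline plus the summed
#'   increments of the subset communities over that baseline (used for
#'   cellulose: mono-culture plus the three bi-culture gains).
#'
#' @param values numeric vector of subset phenotype values.
#' @param scheme `"sum_of_values"` or `"sum_of_increments"`.
#' @param baseline baseline value (required for `"sum_of_increments"`).
#' @param se standard errors of `values` (default 0).
#' @param baseline_se standard error of the baseline.
#' @return List with `expectation` and `se` (root-sum-square propagation).
#' @examples
#' additive_expectation(c(0.16, 0.89), "sum_of_values")
#' additive_expectation(c(197.77, 198.17, 203.73), "sum_of_increments",
#'                      baseline = 184.39)
#' @export
additive_expectation <- function(values,
                                 scheme = c("sum_of_values", "sum_of_increments"),
                                 baseline = NULL, se = 0, baseline_se = 0) {
  scheme <- match.arg(scheme)
  if (!length(values)) stop("no subset values supplied")
  se <- rep_len(se, length(values))
  if (scheme == "sum_of_values") {
    list(expectation = sum(values), se = sqrt(sum(se^2)))
  } else {
    if (is.null(baseline)) stop("'sum_of_increments' needs a baseline")
    # expectation = sum(values) - (n - 1) * baseline
    list(expectation = baseline + sum(values - baseline),
         se = sqrt(sum(se^2) + (length(values) - 1)^2 * baseline_se^2))
  }
}

#' Classify a higher-order interaction as synergy
#'
#' A tertiary interaction is positively synergistic when the observed
#' community phenotype exceeds the additive expectation by more than the
#' propagated uncertainty, negatively synergistic when it falls below it,
#' and additive otherwise.
#'
#' @param observed observed phenotype value.
#' @param expectation additive expectation (e.g. from
#'   [additive_expectation()]).
#' @param uncertainty standard error of the difference (default 0).
#' @param phenotype label carried into the result.
#' @param units unit label.
#' @return An object of class `synergy_result`: `phenotype`, `units`,
#'   `observed`, `expectation`, `difference`, `relative_difference`
#'   (fraction of the expectation; `NA` with a warning when the expectation
#'   is zero), `uncertainty` and `classification`.
#' @examples
#' classify_synergy(1.37, 1.05, 0.036, phenotype = "CH4")
#' @export
classify_synergy <- function(observed, expectation, uncertainty = 0,
                             phenotype = "phenotype", units = "mmol") {
  difference <- observed - expectation
  if (expectation == 0) {
    rel <- if (difference == 0) 0 else NA_real_
    if (is.na(rel)) {
      warning("expectation is zero: relative difference undefined")
    }
  } else {
    rel <- difference / expectation
  }
  classification <- if (difference > uncertainty) "positive"
    else if (difference < -uncertainty) "negative" else "additive"
  structure(
    list(phenotype = phenotype, units = units, observed = observed,
         expectation = expectation, difference = difference,
         relative_difference = rel, uncertainty = uncertainty,
         classification = classification),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4g vs additive %.4g %s -> %s (%+.1f%%, +/- %.2g)\n",
              x$phenotype, x$observed, x$expectation, x$units,
              x$classification, 100 * x$relative_difference, x$uncertainty))
  invisible(x)
}

.balance_sheet <- function(observation, what = c("carbon", "electrons"),
                           products) {
  what <- match.arg(what)
  mets <- metabolite_table()
  col <- if (what == "carbon") "carbon_atoms" else "electron_equivalents"
  nc <- observation$net_change
  unknown <- setdiff(products, mets$id)
  if (length(unknown)) stop("unknown product(s): ", paste(unknown, collapse = ", "))
  products <- intersect(products, names(nc))
  amounts <- pmax(unlist(nc[products]), 0)
  equiv <- mets[[col]][match(products, mets$id)]
  sheet <- data.frame(product = products, amount_mmol = unname(amounts),
                      equivalents = equiv,
                      stringsAsFactors = FALSE)
  sheet[[paste0(what, "_mmol")]] <- sheet$amount_mmol * sheet$equivalents
  total <- sum(sheet[[paste0(what, "_mmol")]])
  if (total > 0) {
    sheet$fraction <- sheet[[paste0(what, "_mmol")]] / total
  } else {
    sheet$fraction <- NA_real_
    attr(sheet, "degenerate") <- TRUE
  }
  attr(sheet, "total") <- total
  class(sheet) <- c("balance_sheet", "data.frame")
  sheet
}

#' Carbon balance sheet of fermentation products
#'
#' Carbon millimoles recovered in each measured product of a culture
#' (amount times carbon atoms per molecule) and each product's fraction of
#' the recovered-product carbon total. Fractions are over recovered products
#' only; assimilation into biomass is not measured and not included in the
#' denominator.
#'
#' @param observation a `culture_observation`.
#' @param products products to include (default: all carbon-bearing measured
#'   products).
#' @return A `balance_sheet` data.frame with columns `product`,
#'   `amount_mmol`, `equivalents`, `carbon_mmol`, `fraction`; the total is
#'   in `attr(, "total")`.
#' @examples
#' carbon_balance(load_observations(synflux_table1())[["quad"]])
#' @export
carbon_balance <- function(observation,
                           products = c("ch4", "co2", "acetate", "lactate",
                                        "ethanol", "glucose", "cellobiose")) {
  .balance_sheet(observation, "carbon", products)
}

#' Electron-equivalent balance sheet of fermentation products
#'
#' Electron millimoles transferred into each product (amount times electron
#' equivalents on the oxidation-to-CO2 basis; sulfate to sulfide carries 8,
#' so the H2S entry books the electrons sunk into sulfate reduction), with
#' fractions of the recovered-product electron total.
#'
#' @param observation a `culture_observation`.
#' @param products products to include.
#' @return A `balance_sheet` data.frame (see [carbon_balance()]) with column
#'   `electrons_mmol`.
#' @examples
#' electron_balance(load_observations(synflux_table1())[["quad_S"]])
#' @export
electron_balance <- function(observation,
                             products = c("ch4", "h2", "acetate", "lactate",
                                          "ethanol", "h2s", "co2")) {
  .balance_sheet(observation, "electrons", products)
}
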