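#' Convert consumed cellulose mass to glucose equivalents
#'
#' Extracellular hydrolysis is omitted from the model: R. cellulolyticum is
#' treated as fermenting the anhydroglucose units of the cellulose it
#' consumed. Masses therefore convert at the anhydroglucose monomer mass of
#' 162.14 g/mol by default; pass `monomer_mass = 180.16` to account in free
#' glucose instead.
#'
#' @param mass_mg consumed cellulose, mg (non-negative).
#' @param monomer_mass g/mol of one glucose unit (default 162.14).
#' @return mmol of glucose equivalents.
#' @examples
#' glucose_from_cellulose(162.14)  # 1 mmol
#' @export
glucose_from_cellulose <- function(mass_mg, monomer_mass = ANHYDROGLUCOSE_MASS) {
  if (any(!is.finite(mass_mg)) || any(mass_mg < 0)) {
    stop("cellulose mass must be finite and non-negative")
  }
  mass_mg / monomer_mass
}

#' Moles of one gas in a serum-bottle headspace
#'
#' Ideal-gas conversion of a measured headspace pressure, volume and
#' temperature to the absolute amount of one component given its mole
#' fraction from GC analysis.
#'
#' @param pressure_kpa absolute pressure, kPa.
#' @param volume_l headspace volume, L.
#' @param temperature_k temperature, K.
#' @param mole_fraction component mole fraction in `[0, 1]`.
#' @return mmol of the gas.
#' @examples
#' headspace_moles(101.325, 0.140, 307.15, 1.0)
#' @export
headspace_moles <- function(pressure_kpa, volume_l, temperature_k, mole_fraction) {
  if (any(pressure_kpa <= 0) || any(volume_l <= 0) || any(temperature_k <= 0)) {
    stop("pressure, volume and temperature must be positive")
  }
  if (any(mole_fraction < 0) || any(mole_fraction > 1)) {
    stop("mole_fraction must lie in [0, 1]")
  }
  R <- 8.314462618  # J / (mol K) == kPa L / (mol K)
  1000 * mole_fraction * pressure_kpa * volume_l / (R * temperature_k)
}

# column layout of the observation CSV dialect (units in the header names)
.obs_value_cols <- c(cellulose = "cellulose_mg", ch4 = "ch4_mmol",
                     co2 = "co2_mmol", h2 = "h2_mmol", h2s = "h2s_mmol",
                     acetate = "acetate_mmol", lactate = "lactate_mmol",
                     glucose = "glucose_umol", cellobiose = "cellobiose_umol")
.obs_flag_cols <- c("Rc", "Mh", "Mc", "Dv", "sulfate")

#' Construct a single culture observation
#'
#' @param culture_id label of the culture.
#' @param species_present character subset of `c("Rc","Mh","Mc","Dv")`.
#' @param sulfate_added logical.
#' @param replicate replicate index, or `"mean"` for replicate-averaged rows.
#' @param cellulose_mg consumed cellulose over the incubation, mg.
#' @param net_change named mmol vector of net changes (accumulation positive)
#'   for `ch4`, `co2`, `h2`, `h2s`, `acetate`, `lactate`, `glucose`,
#'   `cellobiose`. The `h2s` entry doubles as the sulfate consumed, from
#'   which the sulfide accumulation was inferred.
#' @param uncertainty optional named vector of standard errors (mmol; mg for
#'   `cellulose`).
#' @return An object of class `culture_observation`.
#' @export
culture_observation <- function(culture_id, species_present, sulfate_added,
                                replicate = "mean", cellulose_mg,
                                net_change, uncertainty = NULL) {
  stopifnot(is.numeric(cellulose_mg), length(cellulose_mg) == 1L)
  if (cellulose_mg < 0) stop("cellulose_consumed must be >= 0")
  for (m in c("ch4", "h2s")) {
    if (!is.null(net_change[m]) && !is.na(net_change[m]) && net_change[[m]] < -1e-9) {
      stop(m, " accumulation must be >= 0")
    }
  }
  structure(
    list(culture_id = culture_id,
         species_present = unique(as.character(species_present)),
         sulfate_added = isTRUE(sulfate_added),
         replicate = replicate,
         cellulose_mg = cellulose_mg,
         net_change = net_change,
         uncertainty = uncertainty),
    class = "culture_observation"
  )
}

#' @export
print.culture_observation <- function(x, ...) {
  cat(sprintf("<%s> {%s}%s rep=%s  cellulose %.2f mg\n", x$culture_id,
              paste(x$species_present, collapse = ","),
              if (x$sulfate_added) " +SO4" else "", x$replicate,
              x$cellulose_mg))
  print(round(x$net_change, 4))
  invisible(x)
}

.parse_flag <- function(v, col, rows) {
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("yes", "true", "1")] <- TRUE
  out[s %in% c("no", "false", "0")] <- FALSE
  if (anyNA(out)) {
    stop("column '", col, "': unparseable flag in row(s) ",
         paste(rows[is.na(out)], collapse = ", "))
  }
  out
}

#' Read culture observations from CSV
#'
#' One row per culture x replicate. Required columns: `culture_id`,
#' presence flags `Rc`, `Mh`, `Mc`, `Dv`, `sulfate` (yes/no), `replicate`,
#' and the amounts `cellulose_mg`, `ch4_mmol`, `co2_mmol`, `h2_mmol`,
#' `h2s_mmol`, `acetate_mmol`, `lactate_mmol`, `glucose_umol`,
#' `cellobiose_umol`. Micromolar sugar columns are converted to mmol on read.
#' Optional `*_se*` columns carry standard errors. The bundled fixture
#' ([synflux_table1()]) reproduces all 13 cultures of the endpoint
#' measurement table as replicate means.
#'
#' @param path CSV file.
#' @return List of [culture_observation()] objects.
#' @examples
#' obs <- load_observations(synflux_table1())
#' obs[["quad"]]
#' @export
load_observations <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("observation file '", path, "' contains no rows")
  required <- c("culture_id", .obs_flag_cols, "replicate",
                unname(.obs_value_cols))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  rows <- seq_len(nrow(df))
  flags <- lapply(.obs_flag_cols, function(cn) .parse_flag(df[[cn]], cn, rows))
  names(flags) <- .obs_flag_cols
  for (cn in unname(.obs_value_cols)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      stop("column '", cn, "': non-numeric value in row(s) ",
           paste(rows[is.na(v)], collapse = ", "))
    }
    df[[cn]] <- v
  }
  se_cols <- grep("_se(_|$)", names(df), value = TRUE)
  obs <- lapply(rows, function(i) {
    species <- c("Rc", "Mh", "Mc", "Dv")[c(flags$Rc[i], flags$Mh[i],
                                           flags$Mc[i], flags$Dv[i])]
    nc <- c(ch4 = df$ch4_mmol[i], co2 = df$co2_mmol[i], h2 = df$h2_mmol[i],
            h2s = df$h2s_mmol[i], acetate = df$acetate_mmol[i],
            lactate = df$lactate_mmol[i],
            glucose = df$glucose_umol[i] / 1000,
            cellobiose = df$cellobiose_umol[i] / 1000)
    unc <- NULL
    if (length(se_cols)) {
      nm <- sub("_se.*$", "", se_cols)
      unc <- as.numeric(df[i, se_cols])
      names(unc) <- nm
      # sugar SEs arrive in umol like their values
      for (s in intersect(c("glucose", "cellobiose"), nm)) {
        unc[s] <- unc[s] / 1000
      }
    }
    culture_observation(df$culture_id[i], species, flags$sulfate[i],
                        df$replicate[i], df$cellulose_mg[i], nc, unc)
  })
  names(obs) <- vapply(obs, function(o) {
    if (identical(o$replicate, "mean")) o$culture_id
    else paste(o$culture_id, o$replicate, sep = ".")
  }, "")
  obs
}

#' Write culture observations to CSV
#'
#' Inverse of [load_observations()]: numeric fields round-trip at full
#' precision (values are written with 15 significant digits).
#'
#' @param obs list of `culture_observation` objects.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  rows <- lapply(obs, function(o) {
    d <- data.frame(
      culture_id = o$culture_id,
      Rc = "Rc" %in% o$species_present, Mh = "Mh" %in% o$species_present,
      Mc = "Mc" %in% o$species_present, Dv = "Dv" %in% o$species_present,
      sulfate = o$sulfate_added, replicate = o$replicate,
      cellulose_mg = o$cellulose_mg,
      ch4_mmol = o$net_change[["ch4"]], co2_mmol = o$net_change[["co2"]],
      h2_mmol = o$net_change[["h2"]], h2s_mmol = o$net_change[["h2s"]],
      acetate_mmol = o$net_change[["acetate"]],
      lactate_mmol = o$net_change[["lactate"]],
      glucose_umol = o$net_change[["glucose"]] * 1000,
      cellobiose_umol = o$net_change[["cellobiose"]] * 1000,
      stringsAsFactors = FALSE
    )
    if (!is.null(o$uncertainty)) {
      for (m in names(o$uncertainty)) {
        unit <- if (m == "cellulose") "mg" else
          if (m %in% c("glucose", "cellobiose")) "umol" else "mmol"
        val <- o$uncertainty[[m]]
        if (unit == "umol") val <- val * 1000
        d[[paste0(m, "_se_", unit)]] <- val
      }
    }
    d
  })
  df <- do.call(rbind, rows)
  for (cn in names(df)) {
    if (is.logical(df[[cn]])) df[[cn]] <- ifelse(df[[cn]], "yes", "no")
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to the bundled endpoint measurement table
#'
#' Replicate-mean net metabolite changes (with standard errors) of all 13
#' culture compositions after 7 days of incubation, as published for the
#' four-species community.
#'
#' @return File path of `table1.csv` inside the installed package.
#' @export
synflux_table1 <- function() {
  system.file("extdata", "table1.csv", package = "synflux", mustWork = TRUE)
}

#' Net-change vector of an observation, aligned to a model
#'
#' Builds the vector the extents are fitted to. The glucose entry is the
#' consumption implied by the degraded cellulose
#' (`-glucose_from_cellulose(cellulose_mg)`) plus the residual soluble
#' glucose; product entries are the measured accumulations; the `h2s` entry
#' equals the consumed sulfate (from which sulfide was inferred) and the
#' `sulfate` entry carries the same consumption with negative sign. CO2 and
#' sulfate are carried but excluded from the objective by the default
#' weights.
#'
#' @param observation a `culture_observation`.
#' @param model a `community_model`.
#' @param monomer_mass g/mol used for the cellulose conversion.
#' @return Named numeric vector in `model$metabolite_order` (mmol).
#' @examples
#' obs <- load_observations(synflux_table1())
#' m <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), FALSE)
#' net_change_vector(obs[["quad"]], m)
#' @export
net_change_vector <- function(observation, model,
                              monomer_mass = ANHYDROGLUCOSE_MASS) {
  stopifnot(inherits(observation, "culture_observation"),
            inherits(model, "community_model"))
  nc <- observation$net_change
  needed <- c("ch4", "h2", "h2s", "acetate", "lactate", "glucose", "co2")
  miss <- setdiff(needed, names(nc))
  if (length(miss)) {
    stop("observation '", observation$culture_id,
         "' lacks metabolite(s): ", paste(miss, collapse = ", "))
  }
  y <- stats::setNames(numeric(length(model$metabolite_order)),
                       model$metabolite_order)
  y["glucose"] <- -glucose_from_cellulose(observation$cellulose_mg,
                                          monomer_mass) + nc[["glucose"]]
  for (m in c("lactate", "acetate", "h2", "ch4", "co2", "h2s")) {
    y[m] <- nc[[m]]
  }
  y["sulfate"] <- -nc[["h2s"]]
  y
}
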