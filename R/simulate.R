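#' Configuration of the synthetic observation generator
#'
#' Defines a ground-truth scenario: a culture composition, true reaction
#' extents, a per-metabolite Gaussian noise level on the net changes,
#' replicate count and seed, plus an optional per-day extent schedule for
#' daily-cumulative trajectories. Defaults emulate the quad-culture control
#' condition: extents near the best fit to the endpoint table, with the
#' redundant hydrogenic lactate-oxidation route inactive so that the
#' remaining extents are identifiable, and noise at the scale of the
#' published replicate standard errors.
#'
#' @param species_present culture composition (must include `"Rc"`).
#' @param sulfate_present logical.
#' @param extents named true extents (mmol) over the active reactions;
#'   missing reactions default to 0.
#' @param noise per-metabolite noise standard deviation (mmol); a scalar is
#'   recycled over the model's metabolite order.
#' @param replicates replicates per generated culture.
#' @param seed integer seed recorded in the output for reproducibility.
#' @param schedule optional reactions x 7 matrix of non-negative daily
#'   extent fractions, each row summing to 1 (row names = reaction ids).
#' @return An object of class `generator_config`.
#' @examples
#' generator_config(seed = 42)
#' @export
generator_config <- function(species_present = c("Rc", "Mh", "Mc", "Dv"),
                             sulfate_present = FALSE,
                             extents = c(rc_lactate = 0.15,
                                         rc_acetogenesis = 0.82,
                                         dv_lactate_h2 = 0,
                                         mh_methanogenesis = 0.49,
                                         mc_methanogenesis = 0.99),
                             noise = 0.02, replicates = 3, seed = 1L,
                             schedule = NULL) {
  model <- assemble_model(species_present, sulfate_present)
  ids <- names(model$reactions)
  x <- stats::setNames(numeric(length(ids)), ids)
  known <- intersect(names(extents), ids)
  unknown <- setdiff(names(extents), ids)
  if (length(unknown)) {
    stop("extents given for inactive reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  x[known] <- extents[known]
  if (any(x < 0)) stop("extents must be non-negative")
  mets <- model$metabolite_order
  if (is.null(names(noise))) {
    noise <- stats::setNames(rep_len(noise, length(mets)), mets)
  } else {
    full <- stats::setNames(numeric(length(mets)), mets)
    full[intersect(names(noise), mets)] <- noise[intersect(names(noise), mets)]
    noise <- full
  }
  if (any(noise < 0)) stop("noise standard deviations must be >= 0")
  if (!is.null(schedule)) {
    schedule <- as.matrix(schedule)
    if (ncol(schedule) != 7L || is.null(rownames(schedule))) {
      stop("schedule must be a reactions x 7 matrix with reaction row names")
    }
    if (any(schedule < 0) || any(abs(rowSums(schedule) - 1) > 1e-8)) {
      stop("schedule fractions must be non-negative and sum to 1 per reaction")
    }
  }
  structure(
    list(model = model, extents = x, noise = noise,
         replicates = as.integer(replicates), seed = as.integer(seed),
         schedule = schedule),
    class = "generator_config"
  )
}

# noiseless endpoint vector of a config
.true_endpoint <- function(config) {
  as.vector(stoich_matrix(config$model) %*% config$extents)
}

.obs_from_vector <- function(config, y, replicate) {
  mets <- config$model$metabolite_order
  names(y) <- mets
  # physical non-negativity of accumulations; consumption entries keep sign
  floored <- sum(y[c("lactate", "acetate", "h2", "ch4", "co2", "h2s")] < 0)
  for (m in c("lactate", "acetate", "h2", "ch4", "co2", "h2s")) {
    y[m] <- max(y[m], 0)
  }
  o <- culture_observation(
    culture_id = paste0(paste(config$model$species_present, collapse = "_"),
                        if (config$model$sulfate_present) "_S" else ""),
    species_present = config$model$species_present,
    sulfate_added = config$model$sulfate_present,
    replicate = replicate,
    cellulose_mg = max(-y[["glucose"]], 0) * ANHYDROGLUCOSE_MASS,
    net_change = c(ch4 = y[["ch4"]], co2 = y[["co2"]], h2 = y[["h2"]],
                   h2s = y[["h2s"]], acetate = y[["acetate"]],
                   lactate = y[["lactate"]], glucose = 0, cellobiose = 0)
  )
  attr(o, "floored") <- floored
  o
}

#' Generate endpoint observations from known extents
#'
#' Draws `y_rep = S x* + eps`, `eps ~ N(0, diag(noise^2))`, independently per
#' replicate; accumulations are floored at zero (the count of floored values
#' is attached as attribute `"floored"`), and the consumed cellulose mass is
#' back-computed from the glucose entry at 162.14 mg/mmol so the
#' observations round-trip through [net_change_vector()]. Deterministic
#' given `config$seed`; the seed is recorded on the result.
#'
#' @param config a [generator_config()].
#' @return List of `culture_observation` (one per replicate), with
#'   attributes `seed` and `truth` (the noiseless endpoint vector).
#' @export
generate_endpoint <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  y0 <- .true_endpoint(config)
  mets <- config$model$metabolite_order
  out <- withr_seed(config$seed, {
    lapply(seq_len(config$replicates), function(r) {
      eps <- stats::rnorm(length(mets), 0, config$noise)
      .obs_from_vector(config, y0 + eps, replicate = r)
    })
  })
  attr(out, "seed") <- config$seed
  attr(out, "truth") <- stats::setNames(y0, mets)
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate daily-cumulative observations from known extents
#'
#' The cumulative day-d value is `S (x* o cumulative_schedule_d)` plus
#' independent Gaussian noise per day; with zero noise the trajectories of
#' pure products are non-decreasing and day 7 coincides exactly with the
#' endpoint generator.
#'
#' @param config a [generator_config()]; `config$schedule` must be present
#'   (uniform over 7 days via `matrix(1/7, ...)` is a sensible default).
#' @return data.frame in long format: `culture_id`, `replicate`, `day`,
#'   `metabolite`, `cumulative_mmol`.
#' @export
generate_timeseries <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$schedule)) stop("config$schedule is missing")
  S <- stoich_matrix(config$model)
  sched <- config$schedule[colnames(S), , drop = FALSE]
  if (anyNA(sched)) stop("schedule must cover every active reaction")
  csched <- t(apply(sched, 1L, cumsum))
  mets <- config$model$metabolite_order
  cid <- paste0(paste(config$model$species_present, collapse = "_"),
                if (config$model$sulfate_present) "_S" else "")
  withr_seed(config$seed, {
    rows <- list()
    for (r in seq_len(config$replicates)) {
      for (d in 1:7) {
        y <- as.vector(S %*% (config$extents * csched[, d])) +
          stats::rnorm(length(mets), 0, config$noise)
        rows[[length(rows) + 1L]] <- data.frame(
          culture_id = cid, replicate = r, day = d, metabolite = mets,
          cumulative_mmol = y, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate-and-refit recovery experiment
#'
#' Repeats `n_runs` times: generate endpoint replicates from the config's
#' ground truth, average them, rebuild the net-change vector and refit the
#' extents. Reports per-reaction bias and RMSE of the recovered extents and,
#' optionally, the coverage of equal-fit flux ranges (fraction of runs whose
#' range brackets the truth). Run r uses seed `config$seed + r`, so the
#' whole experiment is reproducible.
#'
#' @param config a [generator_config()].
#' @param n_runs number of generate-fit cycles.
#' @param include_ranges also compute per-run flux ranges (slower).
#' @param slack range slack when `include_ranges` (see [flux_range()]).
#' @return An object of class `recovery_report`: data.frame with columns
#'   `reaction`, `true_extent`, `mean_estimate`, `bias`, `rmse` (and
#'   `coverage` when requested); the matrix of per-run estimates is attached
#'   as attribute `"estimates"`.
#' @export
recovery_experiment <- function(config, n_runs = 100, include_ranges = FALSE,
                                slack = 0.05) {
  stopifnot(inherits(config, "generator_config"))
  model <- config$model
  ids <- names(model$reactions)
  est <- matrix(NA_real_, n_runs, length(ids), dimnames = list(NULL, ids))
  covered <- matrix(NA, n_runs, length(ids), dimnames = list(NULL, ids))
  for (run in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + run
    reps <- generate_endpoint(cfg)
    ys <- vapply(reps, function(o) net_change_vector(o, model),
                 numeric(length(model$metabolite_order)))
    y <- rowMeans(ys)
    est[run, ] <- fit_extents(model, y)$extents
    if (include_ranges) {
      for (j in ids) {
        rg <- flux_range(model, y, j, slack = slack)
        covered[run, j] <- config$extents[j] >= rg["min"] - 1e-6 &&
          config$extents[j] <= rg["max"] + 1e-6
      }
    }
  }
  rep <- data.frame(reaction = ids,
                    true_extent = unname(config$extents[ids]),
                    mean_estimate = colMeans(est),
                    bias = colMeans(est) - config$extents[ids],
                    rmse = sqrt(colMeans((t(t(est) - config$extents[ids]))^2)),
                    row.names = NULL)
  if (include_ranges) rep$coverage <- colMeans(covered)
  attr(rep, "estimates") <- est
  class(rep) <- c("recovery_report", "data.frame")
  rep
}
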