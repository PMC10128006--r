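#' Fit non-negative reaction extents to a net-change vector
#'
#' Solves `argmin || W (S x - y) ||_2` subject to `x >= 0` (and `x_r = 0` for
#' explicitly excluded reactions), where `S` is the model's stoichiometric
#' matrix, `y` the observed net changes and `W` a diagonal weight matrix.
#' The problem is convex and solved deterministically by active-set
#' non-negative least squares; no randomness or initialization is involved.
#'
#' @param model a `community_model`.
#' @param y named net-change vector aligned to `model$metabolite_order`
#'   (from [net_change_vector()]).
#' @param weights per-metabolite weights; default 1 on the fitted metabolites
#'   and 0 on CO2 and sulfate ([default_weights()]). For inverse-variance
#'   weighting pass `1/se^2`.
#' @param excluded character vector of reaction ids forced to zero extent.
#' @param normalization NRMSE convention, see [goodness_of_fit()].
#' @return An object of class `flux_fit` with elements `extents` (named mmol,
#'   all >= 0), `predicted` (`S x`), `observed`, `residuals`
#'   (predicted - observed on weighted metabolites), `r_squared`, `nrmse`,
#'   `residual_norm` (weighted), `weights`, `excluded` and `model`.
#' @examples
#' m <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), FALSE)
#' y <- net_change_vector(load_observations(synflux_table1())[["quad"]], m)
#' fit_extents(m, y)
#' @export
fit_extents <- function(model, y, weights = NULL, excluded = character(),
                        normalization = c("mean_abs", "range", "sd")) {
  normalization <- match.arg(normalization)
  S <- stoich_matrix(model)
  if (length(y) != nrow(S)) {
    stop("y has length ", length(y), ", expected ", nrow(S),
         " (model metabolite order)")
  }
  if (!is.null(names(y)) && !identical(names(y), rownames(S))) {
    y <- y[rownames(S)]
    if (anyNA(y)) stop("y is not aligned to the model's metabolite order")
  }
  if (is.null(weights)) weights <- default_weights(model)
  if (length(weights) != nrow(S)) stop("weights must match the metabolite order")
  if (all(weights == 0)) stop("all-zero weight vector: nothing to fit")
  if (any(weights < 0)) stop("weights must be non-negative")
  bad <- setdiff(excluded, colnames(S))
  if (length(bad)) stop("unknown reaction id(s) in 'excluded': ",
                        paste(bad, collapse = ", "))
  free <- setdiff(colnames(S), excluded)
  x <- stats::setNames(numeric(ncol(S)), colnames(S))
  sw <- sqrt(weights)
  Sw <- S * sw
  yw <- as.vector(y * sw)
  if (length(free)) {
    nn <- pracma::lsqnonneg(Sw[, free, drop = FALSE], yw)
    x[free] <- pmax(nn$x, 0)
  }
  predicted <- as.vector(S %*% x)
  names(predicted) <- rownames(S)
  fit <- structure(
    list(model = model, extents = x, predicted = predicted, observed = y,
         weights = weights, excluded = excluded,
         residuals = (predicted - y)[weights > 0],
         residual_norm = sqrt(sum((weights * (predicted - y)^2)[weights > 0])),
         normalization = normalization),
    class = "flux_fit"
  )
  gof <- goodness_of_fit(fit, normalization = normalization)
  fit$r_squared <- gof[["r_squared"]]
  fit$nrmse <- gof[["nrmse"]]
  fit
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("Flux fit: %d reaction(s)%s  R^2 = %.3f, NRMSE = %.3f (%s)\n",
              length(x$extents),
              if (length(x$excluded))
                paste0(" [excluded: ", paste(x$excluded, collapse = ","), "]")
              else "",
              x$r_squared, x$nrmse, x$normalization))
  print(round(x$extents, 4))
  invisible(x)
}

#' Goodness of fit of a flux fit
#'
#' Computed over the metabolites with positive weight only. `r_squared` is
#' `1 - SS_res / SS_tot` about the mean of the observed fitted entries.
#' `nrmse` is the root mean square error normalized by, depending on
#' `normalization`: the mean absolute observed value (`"mean_abs"`, default;
#' stable when some net changes are near zero), the observed range
#' (`"range"`, the convention most common in the forecasting literature), or
#' the observed standard deviation (`"sd"`). `per_metabolite = TRUE`
#' additionally returns each metabolite's |error|/|observed|, skipping
#' zero-valued observations.
#'
#' @param fit a `flux_fit`.
#' @param normalization one of `"mean_abs"`, `"range"`, `"sd"`.
#' @param per_metabolite also return per-metabolite normalized errors.
#' @return Named list with `r_squared`, `nrmse`, `rmse`, and optionally
#'   `per_metabolite`.
#' @export
goodness_of_fit <- function(fit, normalization = c("mean_abs", "range", "sd"),
                            per_metabolite = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(fit, "flux_fit"))
  w <- fit$weights > 0
  if (sum(w) < 2L) stop("R^2 is undefined with fewer than 2 fitted metabolites")
  yf <- fit$observed[w]
  pf <- fit$predicted[w]
  res <- pf - yf
  rmse <- sqrt(mean(res^2))
  denom <- switch(normalization,
                  mean_abs = mean(abs(yf)),
                  range = diff(range(yf)),
                  sd = stats::sd(yf))
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate observations: ", normalization, " normalization is zero")
  }
  ss_tot <- sum((yf - mean(yf))^2)
  out <- list(r_squared = 1 - sum(res^2) / ss_tot,
              nrmse = rmse / denom, rmse = rmse)
  if (per_metabolite) {
    pm <- abs(res) / abs(yf)
    pm[abs(yf) < .Machine$double.eps^ 0.5] <- NA_real_
    out$per_metabolite <- pm
  }
  out
}

#' Pathway-exclusion scan for degenerate flux distributions
#'
#' Refits the model with each reaction sequentially excluded (and, with
#' `max_exclude = 2`, each pair) and compares every refit's NRMSE to the
#' full-model best. A refit is an *equal-fit alternative* when its NRMSE is
#' at most `(1 + tolerance)` times the best NRMSE. Because an excluded
#' reaction may already sit at zero extent, several equal-fit refits can
#' coincide; the number of *distinct* extent vectors among the equal-fit set
#' is reported as `n_distributions`.
#'
#' @param model a `community_model`.
#' @param y net-change vector.
#' @param tolerance relative NRMSE slack defining "equal goodness of fit"
#'   (default 0.05).
#' @param weights optional weights passed to [fit_extents()].
#' @param max_exclude exclusion depth (1 = leave-one-out, matching a
#'   sequential scan; 2 adds all pairs).
#' @return An object of class `flux_distribution_set`: `best` (full-model
#'   fit), `fits` (all refits, named by exclusion), `equal_fit` (the
#'   equal-fit members including the best), `distributions` (matrix of
#'   distinct equal-fit extent vectors, one row each), `n_distributions`,
#'   `ranges` (per-reaction min/max extent over the equal-fit set) and
#'   `tolerance`.
#' @export
exclusion_scan <- function(model, y, tolerance = 0.05, weights = NULL,
                           max_exclude = 1L) {
  stopifnot(length(model$reactions) >= 1L)
  best <- fit_extents(model, y, weights = weights)
  ids <- names(model$reactions)
  excl_sets <- as.list(ids)
  if (max_exclude >= 2L && length(ids) >= 2L) {
    prs <- utils::combn(ids, 2L, simplify = FALSE)
    excl_sets <- c(excl_sets, prs)
  }
  fits <- lapply(excl_sets, function(ex)
    fit_extents(model, y, weights = weights, excluded = ex))
  names(fits) <- vapply(excl_sets, paste, "", collapse = "+")
  all_fits <- c(list(none = best), fits)
  nrmses <- vapply(all_fits, `[[`, 0, "nrmse")
  cutoff <- (1 + tolerance) * best$nrmse + .Machine$double.eps^0.5
  equal <- all_fits[nrmses <= cutoff]
  ext <- do.call(rbind, lapply(equal, `[[`, "extents"))
  distinct <- unique(round(ext, 6L))
  ranges <- data.frame(reaction = colnames(ext),
                       min = apply(ext, 2L, min),
                       max = apply(ext, 2L, max),
                       row.names = NULL)
  structure(
    list(best = best, fits = fits, equal_fit = equal,
         distributions = distinct, n_distributions = nrow(distinct),
         ranges = ranges, tolerance = tolerance,
         nrmse = nrmses),
    class = "flux_distribution_set"
  )
}

#' @export
print.flux_distribution_set <- function(x, ...) {
  cat(sprintf(paste0("Exclusion scan: best NRMSE %.4f; %d equal-fit member(s)",
                     " at tolerance %.0f%%; %d distinct distribution(s)\n"),
              x$best$nrmse, length(x$equal_fit), 100 * x$tolerance,
              x$n_distributions))
  print(round(x$distributions, 4))
  cat("Extent ranges over the equal-fit set:\n")
  print(transform(x$ranges, min = round(min, 4), max = round(max, 4)))
  invisible(x)
}

# min_{x >= 0, c'x = t} ||W(Sx - y)||^2, via a heavily weighted penalty row
.profile_objective <- function(Sw, yw, cvec, t, penalty = 1e8) {
  A <- rbind(Sw, sqrt(penalty) * cvec)
  b <- c(yw, sqrt(penalty) * t)
  x <- pmax(pracma::lsqnonneg(A, b)$x, 0)
  list(obj = sum((Sw %*% x - yw)^2), x = x)
}

# largest (dir = +1) or smallest (dir = -1) feasible t with profile <= bound2
.range_search <- function(Sw, yw, cvec, t0, bound2, dir, tol = 1e-6) {
  # t is bounded below by 0 since cvec >= 0 and x >= 0
  if (dir < 0) {
    if (.profile_objective(Sw, yw, cvec, 0)$obj <= bound2) return(0)
    lo <- 0; hi <- t0          # infeasible at lo, feasible at hi
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.profile_objective(Sw, yw, cvec, mid)$obj <= bound2) hi <- mid
      else lo <- mid
    }
    return(hi)
  }
  step <- max(t0, 1)
  hi <- t0 + step
  while (.profile_objective(Sw, yw, cvec, hi)$obj <= bound2) {
    hi <- hi + step
    step <- step * 2
    if (hi > 1e6) stop("flux range is unbounded above the residual constraint")
  }
  lo <- t0                     # feasible at lo, infeasible at hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.profile_objective(Sw, yw, cvec, mid)$obj <= bound2) lo <- mid
    else hi <- mid
  }
  lo
}

#' Flux range of a linear functional under an equal-fit constraint
#'
#' Minimizes and maximizes `c' x` over `x >= 0` subject to
#' `||W(S x - y)|| <= (1 + slack) * r_best`, where `r_best` is the best-fit
#' weighted residual norm — flux variability analysis on the residual-ball
#' solution set. Each bound is found by bisection on the convex profile
#' `t -> min ||W(Sx - y)||^2` s.t. `c'x = t`.
#'
#' @param model a `community_model`.
#' @param y net-change vector.
#' @param reaction a reaction id (range of that extent); alternatively pass
#'   `coefficients`, a named non-negative vector over reaction ids defining a
#'   derived flux (e.g. `c(dv_h2_sulfate = 4)` for H2 consumed by
#'   sulfidogenic hydrogen oxidation).
#' @param slack relative widening of the best residual norm (default 0.05;
#'   0 restricts to the exact least-squares solution set).
#' @param weights optional fitting weights.
#' @param coefficients see `reaction`.
#' @param tol bisection tolerance on the flux (mmol).
#' @return Named numeric `c(min = , max = )` in mmol.
#' @examples
#' m <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), FALSE)
#' y <- net_change_vector(load_observations(synflux_table1())[["quad"]], m)
#' flux_range(m, y, "dv_lactate_h2")
#' @export
flux_range <- function(model, y, reaction = NULL, slack = 0.05,
                       weights = NULL, coefficients = NULL, tol = 1e-6) {
  if (slack < 0) stop("slack must be >= 0")
  S <- stoich_matrix(model)
  if (is.null(coefficients)) {
    if (is.null(reaction) || !reaction %in% colnames(S)) {
      stop("'reaction' must name an active reaction (or pass 'coefficients')")
    }
    cvec <- stats::setNames(numeric(ncol(S)), colnames(S))
    cvec[reaction] <- 1
  } else {
    bad <- setdiff(names(coefficients), colnames(S))
    if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
    if (any(coefficients < 0)) stop("'coefficients' must be non-negative")
    cvec <- stats::setNames(numeric(ncol(S)), colnames(S))
    cvec[names(coefficients)] <- coefficients
    if (all(cvec == 0)) stop("'coefficients' defines a zero functional")
  }
  best <- fit_extents(model, y, weights = weights)
  if (is.null(weights)) weights <- default_weights(model)
  y <- if (is.null(names(y))) stats::setNames(y, rownames(S)) else y[rownames(S)]
  if (anyNA(y)) stop("y is not aligned to the model's metabolite order")
  sw <- sqrt(weights)
  Sw <- S * sw
  yw <- as.vector(y * sw)
  bound2 <- ((1 + slack) * best$residual_norm)^2 + tol^2
  t0 <- sum(cvec * best$extents)
  c(min = .range_search(Sw, yw, cvec, t0, bound2, dir = -1, tol = tol),
    max = .range_search(Sw, yw, cvec, t0, bound2, dir = +1, tol = tol))
}

#' Range of a species-level metabolite flux
#'
#' Convenience wrapper around [flux_range()] for derived fluxes such as "H2
#' consumed by D. vulgaris": the functional is the species' summed
#' stoichiometric production (or consumption) of the metabolite.
#'
#' @param model a `community_model`.
#' @param y net-change vector.
#' @param species species label.
#' @param metabolite metabolite id.
#' @param direction `"consumption"` or `"production"`.
#' @param ... passed to [flux_range()].
#' @return Named numeric `c(min = , max = )`, mmol of the metabolite.
#' @export
species_flux_range <- function(model, y, species, metabolite,
                               direction = c("consumption", "production"),
                               ...) {
  direction <- match.arg(direction)
  S <- stoich_matrix(model)
  if (!metabolite %in% rownames(S)) stop("unknown metabolite: ", metabolite)
  rids <- species_reactions(model, species)
  if (!length(rids)) stop("species '", species, "' has no active reaction")
  coef <- stats::setNames(S[metabolite, rids], rids)
  coef <- if (direction == "consumption") pmax(-coef, 0) else pmax(coef, 0)
  coef <- coef[coef > 0]
  if (!length(coef)) return(c(min = 0, max = 0))
  flux_range(model, y, coefficients = coef, ...)
}
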