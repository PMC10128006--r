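#' Per-species production and consumption implied by an extent vector
#'
#' Splits each species' reactions into positive (produced) and negative
#' (consumed) stoichiometric parts and scales by the extents:
#' `produced(s, m) = sum over reactions of s of max(coeff, 0) * x_r`, and
#' analogously for consumption.
#'
#' @param model a `community_model`.
#' @param extents named non-negative extent vector over the model's
#'   reactions (e.g. `fit$extents`).
#' @return data.frame with columns `species`, `metabolite`, `produced`,
#'   `consumed` (mmol), one row per species x metabolite with any activity.
#' @export
species_production_consumption <- function(model, extents) {
  S <- stoich_matrix(model)
  extents <- extents[colnames(S)]
  if (anyNA(extents)) stop("extents must be named by the model's reactions")
  if (any(extents < -1e-9)) stop("extents must be non-negative")
  extents <- pmax(extents, 0)
  spec <- vapply(model$reactions, `[[`, "", "species")
  rows <- list()
  for (s in unique(spec)) {
    Ss <- S[, spec == s, drop = FALSE]
    xs <- extents[spec == s]
    produced <- as.vector(pmax(Ss, 0) %*% xs)
    consumed <- as.vector(pmax(-Ss, 0) %*% xs)
    keep <- produced > 0 | consumed > 0
    if (any(keep)) {
      rows[[s]] <- data.frame(species = s,
                              metabolite = rownames(S)[keep],
                              produced = produced[keep],
                              consumed = consumed[keep],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-feeding flux graph of a flux distribution
#'
#' Converts an extent vector into producer-to-consumer transfer edges through
#' the shared, well-mixed metabolite pool. A species' internal turnover of a
#' metabolite (producing and consuming it at once) is netted out first, so a
#' species enters a pool only as a net producer or a net consumer and no
#' self-edges arise. Each net consumer's intake is then attributed to the
#' net producers proportionally to their production shares (the unique
#' symmetric allocation for a single pool); any residual accumulation
#' (production minus consumption) flows to an `"environment"` sink node, and
#' initial availability (e.g. headspace CO2) may be supplied as an
#' `"environment"` source. CO2 edges are model-derived rather than
#' measurement-constrained, since CO2 does not enter the fitting objective.
#'
#' @param model a `community_model`.
#' @param extents named non-negative extent vector.
#' @param initial optional named vector of initially available amounts
#'   (mmol) that consumers may draw beyond community production.
#' @param tol feasibility tolerance (mmol).
#' @return data.frame of edges: `metabolite`, `producer`, `consumer`,
#'   `amount` (mmol). Mass balance holds per metabolite: production (plus
#'   any initial draw) equals the summed out-edges of each producer.
#' @examples
#' m <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), FALSE)
#' y <- net_change_vector(load_observations(synflux_table1())[["quad"]], m)
#' crossfeed_graph(m, fit_extents(m, y)$extents, initial = c(co2 = 1))
#' @export
crossfeed_graph <- function(model, extents, initial = NULL, tol = 1e-6) {
  pc <- species_production_consumption(model, extents)
  # net out within-species turnover: a species is either a net producer or
  # a net consumer of each pool
  net <- pc$produced - pc$consumed
  pc$produced <- pmax(net, 0)
  pc$consumed <- pmax(-net, 0)
  edges <- list()
  for (m in unique(pc$metabolite)) {
    sub <- pc[pc$metabolite == m, , drop = FALSE]
    init <- if (!is.null(initial) && m %in% names(initial)) initial[[m]] else 0
    producers <- sub[sub$produced > 0, c("species", "produced")]
    if (init > 0) {
      producers <- rbind(producers,
                         data.frame(species = "environment", produced = init))
    }
    consumers <- sub[sub$consumed > 0, c("species", "consumed")]
    total_prod <- sum(producers$produced)
    total_cons <- sum(consumers$consumed)
    if (total_cons > total_prod + tol) {
      stop("infeasible extent vector: consumption of '", m, "' (",
           signif(total_cons, 6), " mmol) exceeds production plus initial",
           " availability (", signif(total_prod, 6), " mmol)")
    }
    share <- producers$produced / total_prod
    for (i in seq_len(nrow(consumers))) {
      edges[[length(edges) + 1L]] <- data.frame(
        metabolite = m, producer = producers$species,
        consumer = consumers$species[i],
        amount = consumers$consumed[i] * share,
        stringsAsFactors = FALSE)
    }
    leftover <- total_prod - total_cons
    if (leftover > tol) {
      edges[[length(edges) + 1L]] <- data.frame(
        metabolite = m, producer = producers$species,
        consumer = "environment",
        amount = leftover * share, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, edges)
  out <- out[out$amount > tol, , drop = FALSE]
  out <- out[out$producer != out$consumer, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-feeding edges with ranges over an equal-fit distribution set
#'
#' Builds the cross-feeding graph of every distinct equal-fit flux
#' distribution found by [exclusion_scan()] and reports, per edge, the
#' best-fit amount together with the minimum and maximum over the set
#' (absent edges count as zero).
#'
#' @param model a `community_model`.
#' @param dset a `flux_distribution_set`.
#' @param initial passed to [crossfeed_graph()].
#' @return data.frame with columns `metabolite`, `producer`, `consumer`,
#'   `amount` (best fit), `min`, `max`.
#' @export
crossfeed_ranges <- function(model, dset, initial = NULL) {
  stopifnot(inherits(dset, "flux_distribution_set"))
  graphs <- lapply(seq_len(nrow(dset$distributions)), function(i)
    crossfeed_graph(model, dset$distributions[i, ], initial = initial))
  best <- crossfeed_graph(model, dset$best$extents, initial = initial)
  key <- function(g) paste(g$metabolite, g$producer, g$consumer, sep = "|")
  all_keys <- unique(c(key(best), unlist(lapply(graphs, key))))
  amount_of <- function(g, k) {
    a <- stats::setNames(g$amount, key(g))[k]
    ifelse(is.na(a), 0, a)
  }
  amt <- vapply(graphs, amount_of, numeric(length(all_keys)), k = all_keys)
  amt <- matrix(amt, nrow = length(all_keys))
  best_amt <- amount_of(best, all_keys)
  parts <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  data.frame(metabolite = parts[, 1], producer = parts[, 2],
             consumer = parts[, 3],
             amount = best_amt,
             min = pmin(apply(amt, 1, min), best_amt),
             max = pmax(apply(amt, 1, max), best_amt),
             stringsAsFactors = FALSE)
}

#' Write a cross-feeding edge list as CSV
#'
#' @param edges data.frame from [crossfeed_graph()] or [crossfeed_ranges()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_crossfeed_csv <- function(edges, path) {
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' Export a cross-feeding graph in DOT format
#'
#' Species are nodes, transfers are labeled directed edges; render with
#' Graphviz (`dot -Tsvg`).
#'
#' @param edges data.frame of edges.
#' @param path file to write.
#' @param digits label precision.
#' @return `path`, invisibly.
#' @export
write_crossfeed_dot <- function(edges, path, digits = 3) {
  lines <- c("digraph crossfeeding {", "  rankdir=LR;",
             sprintf("  \"%s\" -> \"%s\" [label=\"%s %s mmol\"];",
                     edges$producer, edges$consumer, edges$metabolite,
                     signif(edges$amount, digits)),
             "}")
  writeLines(lines, path)
  invisible(path)
}
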