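#' Construct a species-attributed overall reaction
#'
#' A reaction couples one species of the community to a set of signed
#' stoichiometric coefficients per unit extent (1 mmol of the reaction as
#' written). Negative coefficients are consumed metabolites, positive ones
#' produced. Water and protons are untracked: they are unmeasured and do not
#' affect any fitted observable.
#'
#' @param id short reaction identifier.
#' @param species one of `"Rc"`, `"Mh"`, `"Mc"`, `"Dv"`.
#' @param stoichiometry named numeric vector of signed coefficients; names
#'   must be metabolite ids from [metabolite_table()].
#' @param requires_sulfate logical; the reaction is removed from models of
#'   sulfate-free cultures.
#' @param label human-readable pathway name.
#' @param check verify carbon and electron-equivalent conservation
#'   (default `TRUE`).
#' @return An object of class `sx_reaction`.
#' @export
reaction <- function(id, species, stoichiometry, requires_sulfate = FALSE,
                     label = id, check = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            species %in% c("Rc", "Mh", "Mc", "Dv"),
            is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  mets <- metabolite_table()
  unknown <- setdiff(names(stoichiometry), mets$id)
  if (length(unknown)) {
    stop("unknown metabolite(s) in reaction '", id, "': ",
         paste(unknown, collapse = ", "))
  }
  rx <- structure(
    list(id = id, species = species, stoichiometry = stoichiometry,
         requires_sulfate = isTRUE(requires_sulfate), label = label),
    class = "sx_reaction"
  )
  if (check) {
    bal <- reaction_balance(rx)
    if (abs(bal["carbon"]) > 1e-9 || abs(bal["electrons"]) > 1e-9) {
      stop("reaction '", id, "' is not balanced: carbon imbalance ",
           bal["carbon"], ", electron imbalance ", bal["electrons"])
    }
  }
  rx
}

#' Carbon and electron imbalance of a reaction
#'
#' @param rx an `sx_reaction`.
#' @return Named numeric vector `c(carbon = , electrons = )`; both are zero
#'   for a conserved reaction.
#' @export
reaction_balance <- function(rx) {
  mets <- metabolite_table()
  idx <- match(names(rx$stoichiometry), mets$id)
  c(carbon = sum(rx$stoichiometry * mets$carbon_atoms[idx]),
    electrons = sum(rx$stoichiometry * mets$electron_equivalents[idx]))
}

#' @export
print.sx_reaction <- function(x, ...) {
  s <- x$stoichiometry
  lhs <- s[s < 0]
  rhs <- s[s > 0]
  fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                  paste(abs(v), names(v))), collapse = " + ")
  cat(sprintf("<%s> [%s] %s: %s -> %s%s\n", x$id, x$species, x$label,
              fmt(lhs), fmt(rhs),
              if (x$requires_sulfate) "  (requires sulfate)" else ""))
  invisible(x)
}

#' The seven overall reactions of the four-species community
#'
#' The registry of documented energy metabolisms used to model the community:
#' two fermentation routes for R. cellulolyticum (glucose stands in for the
#' anhydroglucose units of the consumed cellulose), three for D. vulgaris
#' (hydrogenic lactate oxidation plus the two sulfidogenic oxidations), and
#' one methanogenesis reaction for each methanogen. Coefficients are per
#' 1 mmol extent; every reaction conserves carbon and electron equivalents.
#'
#' @return Named list of [reaction()] objects in registry order.
#' @examples
#' rxns <- default_reactions()
#' sapply(rxns, reaction_balance)
#' @export
default_reactions <- function() {
  rxns <- list(
    reaction("rc_lactate", "Rc",
             c(glucose = -1, lactate = 2),
             label = "lactate fermentation (Rc)"),
    reaction("rc_acetogenesis", "Rc",
             c(glucose = -1, acetate = 2, co2 = 2, h2 = 4),
             label = "hydrogenic acetogenesis (Rc)"),
    reaction("dv_lactate_h2", "Dv",
             c(lactate = -1, acetate = 1, co2 = 1, h2 = 2),
             label = "hydrogenic lactate oxidation (Dv)"),
    reaction("dv_lactate_sulfate", "Dv",
             c(lactate = -2, sulfate = -1, acetate = 2, co2 = 2, h2s = 1),
             requires_sulfate = TRUE,
             label = "sulfidogenic lactate oxidation (Dv)"),
    reaction("dv_h2_sulfate", "Dv",
             c(h2 = -4, sulfate = -1, h2s = 1),
             requires_sulfate = TRUE,
             label = "sulfidogenic hydrogen oxidation (Dv)"),
    reaction("mh_methanogenesis", "Mh",
             c(h2 = -4, co2 = -1, ch4 = 1),
             label = "hydrogenotrophic methanogenesis (Mh)"),
    reaction("mc_methanogenesis", "Mc",
             c(acetate = -1, ch4 = 1, co2 = 1),
             label = "acetoclastic methanogenesis (Mc)")
  )
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  rxns
}

#' Serialize a reaction registry to YAML
#'
#' Lets users override stoichiometries by editing a plain-text config and
#' reading it back with [read_reaction_registry()].
#'
#' @param reactions named list of `sx_reaction` objects.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_reaction_registry <- function(reactions, path) {
  out <- lapply(unname(reactions), function(rx) {
    list(id = rx$id, species = rx$species, label = rx$label,
         requires_sulfate = rx$requires_sulfate,
         stoichiometry = as.list(rx$stoichiometry))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a reaction registry from YAML
#'
#' @param path YAML file written by [write_reaction_registry()] (or edited by
#'   hand). Every reaction is re-validated for carbon and electron
#'   conservation on read.
#' @return Named list of `sx_reaction` objects.
#' @export
read_reaction_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  rxns <- lapply(raw, function(r) {
    reaction(r$id, r$species, unlist(r$stoichiometry),
             requires_sulfate = isTRUE(r$requires_sulfate),
             label = if (is.null(r$label)) r$id else r$label)
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  rxns
}
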