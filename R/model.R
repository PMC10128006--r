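#' Assemble the condition-specific community model
#'
#' Filters the reaction registry down to the reactions expected to be active
#' for a given culture composition: a reaction is active only if its species
#' is present, sulfidogenic reactions are removed when no sulfate is added,
#' and acetoclastic methanogenesis disappears with M. concilii. Registry
#' order is preserved, so the active reaction list (and hence the columns of
#' the stoichiometric matrix) is deterministic.
#'
#' @param species_present character subset of `c("Rc","Mh","Mc","Dv")`; must
#'   contain `"Rc"`, the only species able to attack cellulose.
#' @param sulfate_present logical; were the cultures amended with sulfate?
#' @param reactions reaction registry (default [default_reactions()]).
#' @return An object of class `community_model`: list with elements
#'   `reactions` (active, ordered), `species_present`, `sulfate_present`,
#'   `metabolite_order` and `metabolites` (the registry table).
#' @examples
#' assemble_model(c("Rc", "Mh", "Mc", "Dv"), sulfate_present = FALSE)
#' @export
assemble_model <- function(species_present, sulfate_present,
                           reactions = default_reactions()) {
  species_present <- unique(as.character(species_present))
  bad <- setdiff(species_present, c("Rc", "Mh", "Mc", "Dv"))
  if (length(bad)) stop("unknown species label(s): ", paste(bad, collapse = ", "))
  if (!"Rc" %in% species_present) {
    stop("no primary fermenter: 'Rc' must be present, cellulose is the only substrate")
  }
  stopifnot(is.logical(sulfate_present), length(sulfate_present) == 1L)
  keep <- vapply(reactions, function(rx) {
    rx$species %in% species_present && (sulfate_present || !rx$requires_sulfate)
  }, logical(1))
  structure(
    list(reactions = reactions[keep],
         species_present = species_present,
         sulfate_present = sulfate_present,
         metabolite_order = model_metabolite_order(),
         metabolites = metabolite_table()),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("Community model: {%s}, sulfate %s, %d active reaction(s)\n",
              paste(x$species_present, collapse = ","),
              if (x$sulfate_present) "added" else "absent",
              length(x$reactions)))
  for (rx in x$reactions) print(rx)
  invisible(x)
}

#' Stoichiometric matrix of a community model
#'
#' @param model a `community_model`.
#' @return Numeric matrix, metabolites (rows, in `model$metabolite_order`) by
#'   active reactions (columns, registry order). Entry (m, r) is the signed
#'   coefficient of metabolite m in reaction r per unit extent.
#' @examples
#' stoich_matrix(assemble_model("Rc", FALSE))
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "community_model"))
  mets <- model$metabolite_order
  S <- matrix(0, nrow = length(mets), ncol = length(model$reactions),
              dimnames = list(mets, names(model$reactions)))
  for (rx in model$reactions) {
    s <- rx$stoichiometry[names(rx$stoichiometry) %in% mets]
    S[names(s), rx$id] <- s
  }
  S
}

#' Ids of the reactions a species contributes to a model
#'
#' @param model a `community_model`.
#' @param species species label.
#' @return Character vector of reaction ids (possibly empty).
#' @export
species_reactions <- function(model, species) {
  ids <- vapply(model$reactions, function(rx) rx$species, "")
  names(model$reactions)[ids == species]
}

#' Weights of the fitting objective implied by a model
#'
#' Fitted metabolites (glucose, lactate, acetate, H2, CH4, H2S) get weight 1;
#' carried-but-unfitted rows (CO2, sulfate) get weight 0.
#'
#' @param model a `community_model`.
#' @return Named numeric vector aligned to `model$metabolite_order`.
#' @export
default_weights <- function(model) {
  mets <- model$metabolites
  w <- as.numeric(mets$fitted[match(model$metabolite_order, mets$id)])
  names(w) <- model$metabolite_order
  w
}
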