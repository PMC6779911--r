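#' Compartmentalized stoichiometric metabolic model
#'
#' Holds metabolites (with compartment and carbon/nitrogen atom counts),
#' reactions (bounds, exchange flag), the stoichiometric matrix and the
#' objective reaction. Validity enforces consistent dimensions, `lb <= ub`,
#' participation of every metabolite in at least one reaction, and exact
#' carbon and nitrogen balance of every internal (non-exchange) reaction.
#'
#' @slot metabolites data.frame with `id`, `compartment`, `carbon`,
#'   `nitrogen`.
#' @slot reactions data.frame with `id`, `lower`, `upper`, `exchange`.
#' @slot stoich Numeric matrix, metabolites x reactions.
#' @slot objective Objective reaction id.
#' @exportClass MetabolicModel
setClass("MetabolicModel",
         representation(metabolites = "data.frame",
                        reactions = "data.frame",
                        stoich = "matrix",
                        objective = "character"))

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  S <- object@stoich
  met <- object@metabolites; rxn <- object@reactions
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    return("stoichiometric matrix dimensions do not match annotations")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    return("stoichiometric matrix dimnames do not match ids")
  if (any(rxn$lower > rxn$upper + 1e-12))
    msgs <- c(msgs, "reaction with lower bound above upper bound")
  if (!(object@objective %in% rxn$id))
    msgs <- c(msgs, "objective reaction absent from the model")
  orphan <- rowSums(S != 0) == 0
  if (any(orphan))
    msgs <- c(msgs, paste("metabolites in no reaction:",
                          paste(met$id[orphan], collapse = ", ")))
  for (el in c("carbon", "nitrogen")) {
    bal <- as.vector(t(S) %*% met[[el]])
    bad <- !rxn$exchange & abs(bal) > 1e-9
    if (any(bad))
      msgs <- c(msgs, paste0(el, " imbalance in internal reaction(s): ",
                             paste(rxn$id[bad], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MetabolicModel-class compact display
#' @param object A `MetabolicModel`.
#' @export
setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions (",
      sum(object@reactions$exchange), "exchange ) in compartments",
      paste(sort(unique(object@metabolites$compartment)), collapse = "/"),
      "\n  objective:", object@objective, "\n")
})

#' Flux distribution returned by the FBA solver
#'
#' @slot fluxes Named numeric vector of reaction fluxes
#'   (mmol per gDW per h).
#' @slot objective Objective value.
#' @slot status Solver status string.
#' @exportClass FluxSolution
setClass("FluxSolution",
         representation(fluxes = "numeric", objective = "numeric",
                        status = "character"))

#' @describeIn FluxSolution-class compact display
#' @param object A `FluxSolution`.
#' @export
setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status, "| objective",
      format(object@objective, digits = 6), "|",
      sum(abs(object@fluxes) > 1e-9), "of", length(object@fluxes),
      "reactions carry flux\n")
})

#' Accessors for model and solution objects
#'
#' `reactions()`, `metabolites()`, `stoichiometry()`, `objectiveReaction()`
#' extract the corresponding slots of a [MetabolicModel-class];
#' `fluxes()` the flux vector of a [FluxSolution-class].
#'
#' @param object A `MetabolicModel` or `FluxSolution`.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicModel",
          function(object) object@metabolites)

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object) object@stoich)

#' @rdname accessors
#' @export
setGeneric("objectiveReaction",
           function(object) standardGeneric("objectiveReaction"))
#' @rdname accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel",
          function(object) object@objective)

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)
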