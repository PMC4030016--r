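#' @import methods
#' @importFrom stats setNames cor runif
#' @importFrom utils read.delim write.table head
#' @useDynLib virtumor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.SPECIES_KINDS <- c("protein", "active_form", "complex", "transcript",
                    "metabolite", "drug")
.LAW_FORMS <- c("mass_action", "michaelis_menten", "hill")
.PERTURBATION_KINDS <- c("activating_mutation", "loss_of_function", "deletion",
                         "overexpression", "knockdown", "copy_gain")
.CALLS <- c("sensitive", "resistant")
.DIRECTIONS <- c("sensitizing", "resistance_conferring")
.INDEX_NAMES <- c("proliferation", "survival", "apoptosis", "viability",
                  "relative_growth")

#' NetworkModel: a simulatable reaction network
#'
#' The central container of the package: a set of species (each with an
#' initial amount, a zero-order synthesis rate and a first-order degradation
#' constant, all in dimensionless a.u. and simulated seconds) plus a list of
#' reactions. Each reaction carries reactants/products with integer
#' stoichiometry, optional modifiers (activator/inhibitor with a strength),
#' a kinetic law (`mass_action`, `michaelis_menten` or `hill` with parameters
#' `k`, `Km`, `hill_n`) and a multiplicative `rate_scale` -- the handle that
#' both drugs and genetic perturbations act on.
#'
#' @slot species data.frame with columns `id`, `name`, `kind`,
#'   `initial_amount`, `synthesis_rate`, `degradation_rate`.
#' @slot reactions named list of reaction descriptions (see
#'   [networkReaction()]).
#' @slot metadata list of provenance notes; the reference build also stores
#'   the gene map, species activity/synthesis registries and pathway blocks
#'   here.
#' @export
setClass("NetworkModel",
         representation(species = "data.frame",
                        reactions = "list",
                        metadata = "list"))

setValidity("NetworkModel", function(object) {
  sp <- object@species
  need <- c("id", "name", "kind", "initial_amount", "synthesis_rate",
            "degradation_rate")
  if (!all(need %in% names(sp)))
    return(paste("species table must have columns:", paste(need, collapse = ", ")))
  if (nrow(sp) < 1L) return("model must contain at least one species")
  if (anyDuplicated(sp$id)) return("species ids must be unique")
  if (any(!sp$kind %in% .SPECIES_KINDS))
    return("unknown species kind")
  if (any(!is.finite(sp$initial_amount)) || any(sp$initial_amount < 0))
    return("initial_amount must be finite and >= 0")
  if (any(!is.finite(sp$degradation_rate)) || any(sp$degradation_rate < 0))
    return("degradation_rate must be finite and >= 0")
  if (any(!is.finite(sp$synthesis_rate)) || any(sp$synthesis_rate < 0))
    return("synthesis_rate must be finite and >= 0")
  ids <- sp$id
  rids <- vapply(object@reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids)) return("reaction ids must be unique")
  for (r in object@reactions) {
    msg <- .checkReaction(r, ids)
    if (!isTRUE(msg)) return(msg)
  }
  TRUE
})

.checkReaction <- function(r, species_ids) {
  if (is.null(r$id) || !nzchar(r$id)) return("reaction with empty id")
  for (side in c("reactants", "products")) {
    tab <- r[[side]]
    if (is.null(tab)) next
    if (!all(tab$species %in% species_ids))
      return(sprintf("reaction '%s' references unknown species in %s", r$id, side))
    if (any(tab$stoich < 1) || any(tab$stoich != round(tab$stoich)))
      return(sprintf("reaction '%s': stoichiometry must be integer >= 1", r$id))
  }
  if (!is.null(r$modifiers) && nrow(r$modifiers)) {
    if (!all(r$modifiers$species %in% species_ids))
      return(sprintf("reaction '%s' references unknown modifier species", r$id))
    if (!all(r$modifiers$role %in% c("activator", "inhibitor")))
      return(sprintf("reaction '%s': modifier role must be activator/inhibitor", r$id))
    if (any(r$modifiers$strength <= 0) || any(!is.finite(r$modifiers$strength)))
      return(sprintf("reaction '%s': modifier strength must be finite and > 0", r$id))
  }
  law <- r$law
  if (is.null(law$form) || !law$form %in% .LAW_FORMS)
    return(sprintf("reaction '%s': unknown kinetic law form", r$id))
  p <- law$parameters
  if (is.null(p$k) || !is.finite(p$k) || p$k < 0)
    return(sprintf("reaction '%s': rate constant k must be finite and >= 0", r$id))
  if (law$form %in% c("michaelis_menten", "hill") &&
      (is.null(p$Km) || !is.finite(p$Km) || p$Km <= 0))
    return(sprintf("reaction '%s': Km must be finite and > 0", r$id))
  hn <- if (is.null(p$hill_n)) 1 else p$hill_n
  if (!is.finite(hn) || hn < 1)
    return(sprintf("reaction '%s': hill_n must be finite and >= 1", r$id))
  if (is.null(r$rate_scale) || !is.finite(r$rate_scale) || r$rate_scale < 0)
    return(sprintf("reaction '%s': rate_scale must be finite and >= 0", r$id))
  TRUE
}

#' Construct a reaction description
#'
#' @param id unique reaction id.
#' @param reactants,products named numeric vectors of stoichiometries
#'   (names are species ids), or NULL.
#' @param modifiers data.frame with columns `species`, `role`
#'   (`activator`/`inhibitor`) and `strength`, or NULL.
#' @param law kinetic law form, one of `mass_action`, `michaelis_menten`,
#'   `hill`.
#' @param k,Km,hill_n kinetic parameters; `Km` only used by
#'   Michaelis-Menten/Hill laws, `hill_n` also sets the exponent of the
#'   modifier response curves.
#' @param rate_scale multiplicative factor, the perturbation handle.
#' @return a list understood by [networkModel()].
#' @export
networkReaction <- function(id, reactants = NULL, products = NULL,
                            modifiers = NULL, law = "mass_action",
                            k = 1, Km = 1, hill_n = 1, rate_scale = 1) {
  side <- function(v) {
    if (is.null(v) || !length(v)) return(data.frame(species = character(0),
                                                    stoich = numeric(0)))
    data.frame(species = names(v), stoich = as.numeric(v),
               stringsAsFactors = FALSE)
  }
  if (is.null(modifiers))
    modifiers <- data.frame(species = character(0), role = character(0),
                            strength = numeric(0))
  list(id = id, reactants = side(reactants), products = side(products),
       modifiers = modifiers,
       law = list(form = law, parameters = list(k = k, Km = Km, hill_n = hill_n)),
       rate_scale = rate_scale)
}

#' Construct a NetworkModel
#'
#' @param species data.frame (see [NetworkModel-class]); missing optional
#'   columns are filled with defaults.
#' @param reactions list of reactions built with [networkReaction()].
#' @param metadata list of free-form provenance notes.
#' @return a validated `NetworkModel`.
#' @export
networkModel <- function(species, reactions = list(), metadata = list()) {
  defaults <- list(name = NA_character_, kind = "protein",
                   initial_amount = 0, synthesis_rate = 0, degradation_rate = 0)
  for (col in names(defaults))
    if (is.null(species[[col]])) species[[col]] <- defaults[[col]]
  species$name <- ifelse(is.na(species$name), species$id, species$name)
  names(reactions) <- vapply(reactions, function(r) r$id, character(1))
  new("NetworkModel", species = species, reactions = reactions,
      metadata = metadata)
}

#' CellLineProfile: per-gene aberrations defining an avatar
#'
#' @slot id cell-line name.
#' @slot perturbations data.frame with columns `gene`, `kind`
#'   (one of `activating_mutation`, `loss_of_function`, `deletion`,
#'   `overexpression`, `knockdown`, `copy_gain`) and `magnitude`
#'   (fold factor > 0; ignored for `deletion`).
#' @slot provenance free text.
#' @slot locked locked profiles (post-alignment) are immutable.
#' @export
setClass("CellLineProfile",
         representation(id = "character", perturbations = "data.frame",
                        provenance = "character", locked = "logical"))

setValidity("CellLineProfile", function(object) {
  if (!nzchar(object@id)) return("profile id must be non-empty")
  p <- object@perturbations
  if (!all(c("gene", "kind", "magnitude") %in% names(p)))
    return("perturbations need columns gene, kind, magnitude")
  if (nrow(p)) {
    if (any(!nzchar(p$gene))) return("gene symbols must be non-empty")
    if (any(!p$kind %in% .PERTURBATION_KINDS))
      return(paste("unknown perturbation kind; allowed:",
                   paste(.PERTURBATION_KINDS, collapse = ", ")))
    key <- paste(p$gene, p$kind)
    if (anyDuplicated(key))
      return("at most one perturbation per (gene, kind)")
    nondel <- p$kind != "deletion"
    if (any(nondel & (!is.finite(p$magnitude) | p$magnitude <= 0)))
      return("magnitude must be finite and > 0 (except deletion)")
  }
  TRUE
})

#' Construct a CellLineProfile
#'
#' @param id cell-line name.
#' @param perturbations data.frame with columns `gene`, `kind`, `magnitude`;
#'   NA magnitudes are replaced by the kind's default (5 for
#'   activating_mutation/loss_of_function/knockdown, 3 for
#'   overexpression/copy_gain).
#' @param provenance free text.
#' @param locked whether the profile is locked (immutable).
#' @return a validated `CellLineProfile`.
#' @export
cellLineProfile <- function(id, perturbations = NULL, provenance = "",
                            locked = FALSE) {
  if (is.null(perturbations))
    perturbations <- data.frame(gene = character(0), kind = character(0),
                                magnitude = numeric(0))
  perturbations$magnitude <- ifelse(
    is.na(perturbations$magnitude) & perturbations$kind != "deletion",
    .defaultMagnitude(perturbations$kind), perturbations$magnitude)
  new("CellLineProfile", id = id, perturbations = perturbations,
      provenance = provenance, locked = locked)
}

.defaultMagnitude <- function(kind) {
  unname(c(activating_mutation = 5, loss_of_function = 5, deletion = NA,
           overexpression = 3, knockdown = 5, copy_gain = 3)[kind])
}

#' DrugDefinition: a drug as perturbations of target nodes
#'
#' Each target names a node (a species id, resolved through the model's
#' activity registry to the reactions that node drives, or a reaction id
#' directly), an action (`inhibit`/`activate`), a node potency `K` (a.u.),
#' a maximal fractional effect `Emax` in (0, 1] and a Hill exponent. At dose
#' d an inhibited node's `rate_scale` is multiplied by
#' `1 - Emax * d^n / (d^n + K^n)`, an activated node's by
#' `1 + Emax * d^n / (d^n + K^n)`.
#'
#' @slot name drug name.
#' @slot targets data.frame with columns `node`, `action`, `potency`,
#'   `emax`, `hill_n`.
#' @slot aliases alternative names.
#' @slot note mechanism/citation text.
#' @export
setClass("DrugDefinition",
         representation(name = "character", targets = "data.frame",
                        aliases = "character", note = "character"))

setValidity("DrugDefinition", function(object) {
  t <- object@targets
  if (!all(c("node", "action", "potency", "emax", "hill_n") %in% names(t)))
    return("targets need columns node, action, potency, emax, hill_n")
  if (nrow(t) < 1L) return("a drug needs at least one target")
  if (!all(t$action %in% c("inhibit", "activate")))
    return("target action must be inhibit/activate")
  if (any(t$potency <= 0) || any(!is.finite(t$potency)))
    return("potency K must be finite and > 0")
  if (any(t$emax <= 0) || any(t$emax > 1)) return("Emax must be in (0, 1]")
  if (any(t$hill_n < 1)) return("hill_n must be >= 1")
  TRUE
})

#' Construct a DrugDefinition
#'
#' @param name drug name.
#' @param targets data.frame with columns `node`, `action` and optionally
#'   `potency` (default 1 a.u.), `emax` (default 0.95), `hill_n` (default 1).
#' @param aliases character vector of alternative names.
#' @param note mechanism note.
#' @return a validated `DrugDefinition`.
#' @export
drugDefinition <- function(name, targets, aliases = character(0), note = "") {
  if (is.null(targets$potency)) targets$potency <- 1
  if (is.null(targets$emax)) targets$emax <- 0.95
  if (is.null(targets$hill_n)) targets$hill_n <- 1
  new("DrugDefinition", name = name, targets = targets, aliases = aliases,
      note = note)
}

# ---- generics & accessors ---------------------------------------------------

#' @rdname NetworkModel-class
#' @param object,x a `NetworkModel`.
#' @export
setGeneric("modelSpecies", function(x) standardGeneric("modelSpecies"))
#' @rdname NetworkModel-class
#' @export
setMethod("modelSpecies", "NetworkModel", function(x) x@species)

#' @rdname NetworkModel-class
#' @export
setGeneric("modelReactions", function(x) standardGeneric("modelReactions"))
#' @rdname NetworkModel-class
#' @export
setMethod("modelReactions", "NetworkModel", function(x) x@reactions)

#' @rdname NetworkModel-class
#' @export
setGeneric("modelMetadata", function(x) standardGeneric("modelMetadata"))
#' @rdname NetworkModel-class
#' @export
setMethod("modelMetadata", "NetworkModel", function(x) x@metadata)

#' @rdname NetworkModel-class
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))
#' @rdname NetworkModel-class
#' @export
setMethod("speciesIds", "NetworkModel", function(x) x@species$id)

#' @rdname NetworkModel-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @rdname NetworkModel-class
#' @export
setMethod("reactionIds", "NetworkModel", function(x) names(x@reactions))

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel:", nrow(object@species), "species,",
      length(object@reactions), "reactions\n")
  kinds <- table(object@species$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = ":", collapse = " "), "\n")
  if (!is.null(object@metadata$version))
    cat("  version:", object@metadata$version, "\n")
  if (!is.null(object@metadata$profile_id))
    cat("  avatar of:", object@metadata$profile_id, "\n")
})

#' @rdname CellLineProfile-class
#' @param object,x a `CellLineProfile`.
#' @export
setGeneric("profileId", function(x) standardGeneric("profileId"))
#' @rdname CellLineProfile-class
#' @export
setMethod("profileId", "CellLineProfile", function(x) x@id)

#' @rdname CellLineProfile-class
#' @export
setGeneric("perturbations", function(x) standardGeneric("perturbations"))
#' @rdname CellLineProfile-class
#' @export
setMethod("perturbations", "CellLineProfile", function(x) x@perturbations)

#' @rdname CellLineProfile-class
#' @export
setGeneric("isLocked", function(x) standardGeneric("isLocked"))
#' @rdname CellLineProfile-class
#' @export
setMethod("isLocked", "CellLineProfile", function(x) x@locked)

setMethod("show", "CellLineProfile", function(object) {
  cat("CellLineProfile:", object@id,
      if (object@locked) "(locked)" else "", "\n")
  p <- object@perturbations
  if (nrow(p)) {
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %s %s x%s\n", p$gene[i], p$kind[i],
                  format(p$magnitude[i], digits = 3)))
  } else cat("  (no perturbations)\n")
})

#' @rdname DrugDefinition-class
#' @param object,x a `DrugDefinition`.
#' @export
setGeneric("drugName", function(x) standardGeneric("drugName"))
#' @rdname DrugDefinition-class
#' @export
setMethod("drugName", "DrugDefinition", function(x) x@name)

#' @rdname DrugDefinition-class
#' @export
setGeneric("drugTargets", function(x) standardGeneric("drugTargets"))
#' @rdname DrugDefinition-class
#' @export
setMethod("drugTargets", "DrugDefinition", function(x) x@targets)

setMethod("show", "DrugDefinition", function(object) {
  cat("DrugDefinition:", object@name, "\n")
  t <- object@targets
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %s %s (K=%g, Emax=%g, n=%g)\n", t$action[i], t$node[i],
                t$potency[i], t$emax[i], t$hill_n[i]))
})
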