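# Drugs as dose-dependent perturbations of their target reaction nodes.
# Doses are post-ADME concentrations in a.u.; with the default node potency
# K = 1 a.u., a relative dose of 1.0 represents the 1 uM in vitro screen.

.fracEffect <- function(dose, K, emax, n) {
  if (dose <= 0) return(0)
  dn <- dose^n
  emax * dn / (dn + K^n)
}

# Resolve a target node to reaction ids: a reaction id passes through, a
# species id resolves to its registered activity reactions.
.resolveNode <- function(model, node) {
  if (node %in% names(model@reactions)) return(node)
  rx <- model@metadata$act_map[[node]]
  if (is.null(rx) && node %in% model@species$id)
    rx <- model@metadata$syn_map[[node]]
  if (is.null(rx) || !length(rx))
    stop("drug target node '", node, "' cannot be resolved in this model")
  rx
}

#' Apply a drug to a model at a given dose
#'
#' Each inhibited node's reactions get `rate_scale` multiplied by
#' `1 - Emax * d^n / (d^n + K^n)`; activated nodes by `1 + Emax * d^n /
#' (d^n + K^n)`. Dose 0 leaves the model unchanged; at `d = K` with
#' `Emax = 1, n = 1` an inhibited node is exactly halved; as the dose grows
#' the scale approaches `1 - Emax`.
#'
#' @param model a [NetworkModel-class].
#' @param drug a [DrugDefinition-class] (or NULL for no perturbation).
#' @param dose nonnegative post-ADME concentration (a.u.).
#' @return the perturbed model (input untouched).
#' @export
applyDrug <- function(model, drug, dose) {
  if (is.null(drug)) return(model)
  stopifnot(is(model, "NetworkModel"), is(drug, "DrugDefinition"),
            is.finite(dose), dose >= 0)
  if (dose == 0) return(model)
  t <- drug@targets
  for (i in seq_len(nrow(t))) {
    eff <- .fracEffect(dose, t$potency[i], t$emax[i], t$hill_n[i])
    fac <- if (t$action[i] == "inhibit") 1 - eff else 1 + eff
    rx <- .resolveNode(model, t$node[i])
    model <- scaleReactionNodes(model, setNames(rep(fac, length(rx)), rx))
  }
  model@metadata$drug <- list(name = drug@name, dose = dose)
  model
}

.DRUG_LIBRARY_SPEC <- list(
  list(name = "erlotinib", nodes = "EGFR",
       note = "EGFR tyrosine kinase inhibitor; alignment drug"),
  list(name = "lapatinib", nodes = c("EGFR", "ERBB2"),
       note = "dual EGFR/ERBB2 (HER2) kinase inhibitor"),
  list(name = "BIBW2992", nodes = c("EGFR", "ERBB2"), emax = 0.99,
       aliases = "afatinib",
       note = "irreversible EGFR/ERBB2 inhibitor; modeled reversible with high Emax"),
  list(name = "AZD6244", nodes = "MEK", aliases = c("AZD2644", "selumetinib"),
       note = "MEK1/2 inhibitor"),
  list(name = "sorafenib", nodes = c("BRAF", "VEGFR", "PDGFR"),
       note = "multi-kinase RAF/VEGFR/PDGFR inhibitor; alignment drug"),
  list(name = "dasatinib", nodes = c("SRC", "ABL"),
       note = "SRC/ABL inhibitor; alignment drug"),
  list(name = "nilotinib", nodes = c("ABL", "KIT", "PDGFR"),
       note = "ABL/KIT/PDGFR inhibitor"),
  list(name = "imatinib", nodes = c("ABL", "KIT", "PDGFR"),
       note = "ABL/KIT/PDGFR inhibitor"),
  list(name = "sunitinib", nodes = c("VEGFR", "PDGFR", "KIT"),
       note = "multi-RTK inhibitor"),
  list(name = "PD0332991", nodes = "CDK4_CCND1", aliases = "palbociclib",
       note = "CDK4/6-cyclin D1 inhibitor (blocks active complex formation)"),
  list(name = "bortezomib", nodes = "PSM",
       note = "proteasome inhibitor (stabilizes IkB, NOXA, p53)"),
  list(name = "everolimus", nodes = "MTOR", note = "mTORC1 inhibitor"),
  list(name = "celecoxib", nodes = "COX2", note = "COX2 inhibitor"),
  list(name = "pitavastatin", nodes = "HMGCR",
       note = "HMG-CoA reductase inhibitor (blocks mevalonate-dependent RAS prenylation)"))

#' The built-in drug library
#'
#' Fourteen targeted agents, each defined by its target nodes in the
#' reference network with default node potency K = 1 a.u., Emax = 0.95
#' (0.99 for the irreversible-type BIBW2992) and Hill exponent 1. A user
#' JSON (same schema as [writeDrugLibraryJSON()]) may extend or override
#' entries by name.
#'
#' @param extra optional path to a user drug-library JSON.
#' @return named list of [DrugDefinition-class].
#' @export
drugLibrary <- function(extra = NULL) {
  lib <- lapply(.DRUG_LIBRARY_SPEC, function(d) {
    drugDefinition(d$name,
                   data.frame(node = d$nodes, action = "inhibit",
                              potency = 1,
                              emax = if (is.null(d$emax)) 0.95 else d$emax,
                              hill_n = 1, stringsAsFactors = FALSE),
                   aliases = if (is.null(d$aliases)) character(0) else d$aliases,
                   note = d$note)
  })
  names(lib) <- vapply(lib, function(d) d@name, character(1))
  if (anyDuplicated(names(lib))) stop("duplicate drug names in library")
  if (!is.null(extra)) {
    usr <- readDrugLibraryJSON(extra)
    for (nm in names(usr)) lib[[nm]] <- usr[[nm]]
  }
  lib
}

#' Look up a drug by name or alias
#'
#' @param name drug name or alias (case-insensitive).
#' @param library a library from [drugLibrary()].
#' @return a [DrugDefinition-class].
#' @export
getDrug <- function(name, library = drugLibrary()) {
  lc <- tolower(name)
  for (d in library)
    if (lc == tolower(d@name) || lc %in% tolower(d@aliases)) return(d)
  stop("unknown drug '", name, "'; library has: ",
       paste(names(library), collapse = ", "))
}

#' Read / write a drug library JSON
#'
#' Schema: an array of `{name, targets: [{node, action, potency, emax,
#' hill_n}], aliases, note}` objects.
#'
#' @param path file path.
#' @return `readDrugLibraryJSON`: named list of [DrugDefinition-class].
#' @export
readDrugLibraryJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- lapply(j, function(d) {
    t <- do.call(rbind, lapply(d$targets, function(x)
      data.frame(node = x$node, action = x$action,
                 potency = if (is.null(x$potency)) 1 else x$potency,
                 emax = if (is.null(x$emax)) 0.95 else x$emax,
                 hill_n = if (is.null(x$hill_n)) 1 else x$hill_n,
                 stringsAsFactors = FALSE)))
    drugDefinition(d$name, t,
                   aliases = as.character(unlist(d$aliases)),
                   note = if (is.null(d$note)) "" else d$note)
  })
  setNames(lib, vapply(lib, function(d) d@name, character(1)))
}

#' @rdname readDrugLibraryJSON
#' @param library named list of [DrugDefinition-class].
#' @export
writeDrugLibraryJSON <- function(library, path) {
  j <- lapply(library, function(d) {
    t <- d@targets
    list(name = d@name,
         targets = lapply(seq_len(nrow(t)), function(i) as.list(t[i, ])),
         aliases = as.list(d@aliases), note = d@note)
  })
  jsonlite::write_json(unname(j), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
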