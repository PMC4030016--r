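# Turning gene-level perturbation profiles into disease-triggered avatars.
#
# Mapping semantics (multiplicative edits on reaction rate_scale):
#   activating_mutation -> activity reactions x magnitude (default 5)
#   loss_of_function    -> activity reactions x 1/magnitude (default 1/5)
#   overexpression      -> synthesis reactions x magnitude (default 3)
#   copy_gain           -> synthesis reactions x magnitude (default 3)
#   knockdown           -> synthesis reactions x 1/magnitude (default 1/5)
#   deletion            -> synthesis reactions x 0.01 (expression floor)
# Genes whose product has no explicit activation reaction (pure effectors)
# fall back to their synthesis reactions for activity edits. Declared
# unmapped genes (e.g. RUNX3) yield an empty edit list plus a logged notice.

#' Translate one genetic perturbation into reaction edits
#'
#' @param p one-row data.frame (or list) with `gene`, `kind`, `magnitude`.
#' @param model the reference network (carries the gene map and reaction
#'   registries in metadata).
#' @return named numeric vector of rate_scale factors (names = reaction
#'   ids); empty (with a message) for declared-unmapped genes. The attribute
#'   `"notice"` carries any log line.
#' @export
perturbationEdits <- function(p, model) {
  meta <- model@metadata
  gene <- p$gene; kind <- p$kind; mag <- p$magnitude
  if (kind != "deletion") {
    if (is.na(mag)) mag <- .defaultMagnitude(kind)
    if (!is.finite(mag) || mag <= 0) stop("magnitude must be > 0 for ", gene)
  }
  if (gene %in% meta$unmapped_genes) {
    notice <- sprintf("gene '%s' is declared unmapped; perturbation ignored", gene)
    message(notice)
    out <- numeric(0)
    attr(out, "notice") <- notice
    return(out)
  }
  sp_id <- meta$gene_map[[gene]]
  if (is.null(sp_id))
    stop("gene '", gene, "' does not resolve to a network node and is not ",
         "declared unmapped")
  syn <- meta$syn_map[[sp_id]]
  act <- meta$act_map[[sp_id]]
  if (!length(act)) act <- syn  # effector fallback
  edits <- switch(kind,
    activating_mutation = setNames(rep(mag, length(act)), act),
    loss_of_function = setNames(rep(1 / mag, length(act)), act),
    overexpression = setNames(rep(mag, length(syn)), syn),
    copy_gain = setNames(rep(mag, length(syn)), syn),
    knockdown = setNames(rep(1 / mag, length(syn)), syn),
    deletion = setNames(rep(0.01, length(syn)), syn),
    stop("unknown perturbation kind: ", kind))
  if (!length(edits))
    warning("gene '", gene, "' maps to species '", sp_id,
            "' with no registered reactions")
  edits
}

#' Create a cell-line avatar from a profile
#'
#' Applies every perturbation of the profile to the reference network
#' (multiplicative, so the result is order-independent across perturbations)
#' and records the profile id in the metadata. The input model is untouched.
#'
#' @param model the reference network.
#' @param profile a [CellLineProfile-class].
#' @return the perturbed [NetworkModel-class].
#' @export
createAvatar <- function(model, profile) {
  stopifnot(is(model, "NetworkModel"), is(profile, "CellLineProfile"))
  p <- profile@perturbations
  notices <- character(0)
  for (i in seq_len(nrow(p))) {
    edits <- perturbationEdits(p[i, ], model)
    if (!is.null(attr(edits, "notice")))
      notices <- c(notices, attr(edits, "notice"))
    if (length(edits)) model <- scaleReactionNodes(model, edits)
  }
  model@metadata$profile_id <- profile@id
  model@metadata$log <- c(model@metadata$log, notices)
  model
}

#' Add or remove a perturbation from a profile
#'
#' Mirrors the wild-type-variant construction: removing an aberration keeps
#' the rest of the mutation definition intact and suffixes the id (e.g.
#' `"DU145_WT_RB1"`). Locked profiles cannot be edited.
#'
#' @param profile a [CellLineProfile-class] (unlocked).
#' @param remove optional `c(gene, kind)` key of the perturbation to drop.
#' @param add optional one-row data.frame (`gene`, `kind`, `magnitude`).
#' @return a new [CellLineProfile-class].
#' @export
makeVariant <- function(profile, remove = NULL, add = NULL) {
  if (profile@locked) stop("profile '", profile@id, "' is locked")
  p <- profile@perturbations
  id <- profile@id
  if (!is.null(remove)) {
    hit <- p$gene == remove[1] & p$kind == remove[2]
    if (!any(hit))
      stop("profile '", id, "' has no perturbation (", remove[1], ", ",
           remove[2], ")")
    p <- p[!hit, , drop = FALSE]
    id <- paste0(id, "_WT_", remove[1])
  }
  if (!is.null(add)) {
    add <- as.data.frame(add, stringsAsFactors = FALSE)
    p <- rbind(p, add[, c("gene", "kind", "magnitude")])
    id <- paste0(id, "_", add$gene[1])
  }
  rownames(p) <- NULL
  cellLineProfile(id, p, provenance = profile@provenance)
}

#' Read / write cell-line profile tables
#'
#' Tab-separated with columns `cell_line, gene, kind, magnitude`; one row
#' per perturbation, empty magnitude for deletions. The loader validates the
#' perturbation vocabulary and returns one profile per cell line.
#'
#' @param path file path.
#' @return `readProfileTSV`: named list of [CellLineProfile-class].
#' @export
readProfileTSV <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "gene", "kind", "magnitude")
  if (!all(need %in% names(tab)))
    stop("profile TSV needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$kind), .PERTURBATION_KINDS)
  if (length(bad))
    stop("unknown perturbation kind(s): ", paste(bad, collapse = ", "))
  by_line <- split(tab, tab$cell_line)
  out <- lapply(names(by_line), function(id) {
    d <- by_line[[id]]
    cellLineProfile(id, data.frame(gene = d$gene, kind = d$kind,
                                   magnitude = as.numeric(d$magnitude),
                                   stringsAsFactors = FALSE))
  })
  setNames(out, names(by_line))
}

#' @rdname readProfileTSV
#' @param profiles list of [CellLineProfile-class].
#' @export
writeProfileTSV <- function(profiles, path) {
  rows <- lapply(profiles, function(pr) {
    p <- pr@perturbations
    if (!nrow(p)) return(NULL)
    data.frame(cell_line = pr@id, gene = p$gene, kind = p$kind,
               magnitude = p$magnitude, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
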