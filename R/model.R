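# Reaction data model: structure components, reaction records, normalization.

#' Create a structure component
#'
#' One reaction participant.  A component either carries a standard InChI
#' (with optional AuxInfo and InChIKey) or is a *no-structure* component: a
#' material, such as a heterogeneous metal or an enzyme, that has no
#' InChI-representable structure.  No-structure components are counted per
#' layer in the sixth RInChI layer rather than identified.
#'
#' @param molfile Optional V2000 molfile block the component came from.
#' @param inchi Standard InChI string (must begin `"InChI=1S/"`), or `NULL`
#'   for a no-structure component.
#' @param auxinfo Optional InChI AuxInfo string.
#' @param inchikey Optional 27-character standard InChIKey.
#' @return A list of class `structure_component` with fields `molfile`,
#'   `inchi`, `auxinfo`, `inchikey` and `no_structure`.
#' @export
structure_component <- function(molfile = NULL, inchi = NULL, auxinfo = NULL,
                                inchikey = NULL) {
  no_structure <- is.null(inchi)
  if (!no_structure) {
    if (!is_string(inchi) || !startsWith(inchi, "InChI=1S/")) {
      stop_rxnid("only standard InChIs (prefix 'InChI=1S/') are accepted, got: ",
                 if (is_string(inchi)) inchi else "<non-string>",
                 class = "rxnid_inchi_error")
    }
  }
  if (!is.null(inchikey) &&
      !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", inchikey)) {
    stop_rxnid("malformed InChIKey: ", inchikey, class = "rxnid_inchi_error")
  }
  structure(
    list(molfile = molfile, inchi = inchi, auxinfo = auxinfo,
         inchikey = inchikey, no_structure = no_structure),
    class = "structure_component"
  )
}

#' @export
print.structure_component <- function(x, ...) {
  if (x$no_structure) {
    cat("<structure_component: no-structure>\n")
  } else {
    cat("<structure_component>", x$inchi, "\n")
    if (!is.null(x$inchikey)) cat("  ", x$inchikey, "\n")
  }
  invisible(x)
}

as_component <- function(x) {
  if (inherits(x, "structure_component")) return(x)
  if (is_string(x)) {
    if (startsWith(x, "InChI=")) return(structure_component(inchi = x))
    return(molfile_to_identity(x))  # assume a molfile block
  }
  stop_rxnid("cannot interpret a ", class(x)[1],
             " as a reaction component", class = "rxnid_model_error")
}

as_component_list <- function(x) {
  if (is.null(x)) return(list())
  if (inherits(x, "structure_component")) return(list(x))
  if (is.character(x)) x <- as.list(x)
  # identify molfile strings in one batched engine pass
  is_mol <- vapply(x, function(e) is_string(e) && !startsWith(e, "InChI="),
                   logical(1))
  out <- vector("list", length(x))
  if (any(is_mol)) {
    mols <- unlist(x[is_mol], use.names = FALSE)
    for (m in mols) molfile_counts(m)  # validate before the engine sees them
    ids <- identify_molfiles(mols)
    out[is_mol] <- lapply(seq_along(mols), function(i) {
      id <- ids[[i]]
      structure_component(
        molfile = mols[i],
        inchi = if (is.na(id$inchi)) NULL else id$inchi,
        auxinfo = if (is.na(id$auxinfo)) NULL else id$auxinfo,
        inchikey = if (is.na(id$inchikey)) NULL else id$inchikey
      )
    })
  }
  out[!is_mol] <- lapply(x[!is_mol], as_component)
  out
}

rxnid_directions <- c("forward", "backward", "equilibrium", "unspecified")

#' Create a reaction record
#'
#' The pre-serialization reaction model: three groups of components
#' (reactants, products, agents) plus a direction mark.  Agents are substances
#' present both at the beginning and at the end of the reaction (catalysts,
#' solvents).  Any group may be empty; a half-reaction is a valid record.
#'
#' Components may be given as `structure_component` objects, molfile blocks
#' (run through the InChI engine), or standard InChI strings.
#'
#' @param reactants,products,agents Lists (or character vectors) of
#'   components; see above for the accepted forms.
#' @param direction One of `"forward"`, `"backward"`, `"equilibrium"`,
#'   `"unspecified"`.
#' @return A list of class `reaction_record`.
#' @seealso [normalize_record()], [rinchi()], [read_rxn()]
#' @export
reaction_record <- function(reactants = list(), products = list(),
                            agents = list(), direction = "forward") {
  direction <- match.arg(direction, rxnid_directions)
  structure(
    list(reactants = as_component_list(reactants),
         products = as_component_list(products),
         agents = as_component_list(agents),
         direction = direction),
    class = "reaction_record"
  )
}

#' @export
print.reaction_record <- function(x, ...) {
  arrow <- switch(x$direction, forward = "-->", backward = "<--",
                  equilibrium = "<=>", unspecified = "-?-")
  cat(sprintf("<reaction_record> %d reactant(s) %s %d product(s), %d agent(s)\n",
              length(x$reactants), arrow, length(x$products), length(x$agents)))
  invisible(x)
}

group_inchis <- function(comps) {
  vapply(comps, function(c) if (c$no_structure) NA_character_ else c$inchi,
         character(1))
}

# Drop later copies of the same InChI within one group.  No-structure
# components have no identity and are never merged with each other.
dedupe_group <- function(comps) {
  keys <- group_inchis(comps)
  keep <- is.na(keys) | !duplicated(keys, incomparables = NA)
  comps[keep]
}

#' Normalize a reaction record
#'
#' Applies the duplicate rules required before a RInChI can be serialized:
#' duplicates within each group are collapsed to one copy (keyed on the full
#' InChI string, so different drawings of the same molecule collapse); any
#' InChI present in both reactants and products is removed from both and added
#' once to the agents; agents are deduplicated.  No-structure components are
#' never merged and never move between groups.  The direction is unchanged.
#'
#' The operation is idempotent, and the released reference software's
#' behaviour of skipping this check can be emulated with `enabled = FALSE`
#' (for byte-compatibility experiments).
#'
#' @param record A [reaction_record()].
#' @param enabled If `FALSE`, return the record untouched.
#' @return A normalized `reaction_record`.
#' @export
normalize_record <- function(record, enabled = TRUE) {
  stopifnot(inherits(record, "reaction_record"))
  if (!enabled) return(record)

  reactants <- dedupe_group(record$reactants)
  products <- dedupe_group(record$products)
  agents <- dedupe_group(record$agents)

  r_keys <- group_inchis(reactants)
  p_keys <- group_inchis(products)
  common <- intersect(r_keys[!is.na(r_keys)], p_keys[!is.na(p_keys)])
  if (length(common)) {
    moved <- reactants[match(common, r_keys)]
    reactants <- reactants[!(r_keys %in% common)]
    products <- products[!(p_keys %in% common)]
    agents <- dedupe_group(c(agents, moved))
  }

  structure(
    list(reactants = reactants, products = products, agents = agents,
         direction = record$direction),
    class = "reaction_record"
  )
}
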