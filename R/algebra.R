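# Reaction algebra: multistep addition and key-based comparison.

comp_keys <- function(comps) {
  vapply(comps, function(c) if (c$no_structure) NA_character_ else c$inchi,
         character(1))
}

comp_without <- function(comps, drop_inchis) {
  keys <- comp_keys(comps)
  comps[is.na(keys) | !(keys %in% drop_inchis)]
}

# Set-algebra sum of two forward-oriented records: intermediates produced by
# step 1 and consumed by step 2 cancel and are dropped; everything else keeps
# its role.  Agents are species present at both ends of their step, so they
# enter the flow on both sides (R∪A, P∪A); whatever the sum leaves on both
# sides comes out as an agent again.  Folding agents through the flow keeps
# the operation well-behaved across serialization boundaries (an agent
# consumed by a later step correctly turns into a net reactant).
# Stoichiometry-free by construction: groups are InChI sets, so partial
# stoichiometric cancellation cannot be expressed.
add_records <- function(rec1, rec2) {
  stopifnot(inherits(rec1, "reaction_record"), inherits(rec2, "reaction_record"))
  rec1 <- orient_forward(rec1)
  rec2 <- orient_forward(rec2)
  ns <- function(comps) Filter(function(c) c$no_structure, comps)
  st <- function(comps) Filter(function(c) !c$no_structure, comps)
  r1 <- dedupe_group(c(st(rec1$reactants), st(rec1$agents)))
  p1 <- dedupe_group(c(st(rec1$products), st(rec1$agents)))
  r2 <- dedupe_group(c(st(rec2$reactants), st(rec2$agents)))
  p2 <- dedupe_group(c(st(rec2$products), st(rec2$agents)))
  R <- dedupe_group(c(r1, comp_without(r2, comp_keys(p1))))
  P <- dedupe_group(c(p2, comp_without(p1, comp_keys(r2))))
  common <- intersect(comp_keys(R), comp_keys(P))
  structure(
    list(reactants = c(comp_without(R, common),
                       ns(rec1$reactants), ns(rec2$reactants)),
         products = c(comp_without(P, common),
                      ns(rec1$products), ns(rec2$products)),
         agents = c(R[comp_keys(R) %in% common],
                    ns(rec1$agents), ns(rec2$agents)),
         direction = "forward"),
    class = "reaction_record"
  )
}

orient_forward <- function(record) {
  switch(record$direction,
    forward = ,
    unspecified = {
      record$direction <- "forward"
      record
    },
    backward = {
      structure(list(reactants = record$products, products = record$reactants,
                     agents = record$agents, direction = "forward"),
                class = "reaction_record")
    },
    equilibrium = stop_rxnid(
      "cannot add an equilibrium step: re-orient it explicitly first",
      class = "rxnid_algebra_error")
  )
}

layers_to_record <- function(layers) {
  comp_from_row <- function(df, i) {
    structure_component(
      inchi = inchi_unbody(df$body[i]),
      auxinfo = if (is.na(df$auxinfo[i])) NULL else df$auxinfo[i],
      inchikey = if (is.na(df$inchikey[i])) NULL else df$inchikey[i]
    )
  }
  grab <- function(df, n_nostruct) {
    comps <- lapply(seq_len(nrow(df)), function(i) comp_from_row(df, i))
    c(comps, replicate(n_nostruct, structure_component(), simplify = FALSE))
  }
  a <- grab(layers$group_a, layers$u[1])
  b <- grab(layers$group_b, layers$u[2])
  g <- grab(layers$agents, layers$u[3])
  direction <- switch(
    ifelse(is.na(layers$direction), "na", layers$direction),
    "+" = "forward", "-" = "backward", "=" = "equilibrium", na = "unspecified"
  )
  # layer 2 plays the reactant role; a "-" flag marks layer 3 as the start
  if (identical(direction, "backward")) {
    structure(list(reactants = b, products = a, agents = g,
                   direction = "forward"), class = "reaction_record")
  } else {
    structure(list(reactants = a, products = b, agents = g,
                   direction = direction), class = "reaction_record")
  }
}

#' Add two RInChIs (multistep reaction composition)
#'
#' Combines two reaction steps into the single overall reaction: reactants of
#' the sum are the first step's reactants plus any second-step reactants not
#' produced by step one; products are the second step's products plus any
#' first-step products not consumed by step two; intermediates cancel and are
#' dropped; agents are pooled.  No-structure counts add per layer.  Backward
#' steps are re-oriented before addition; equilibrium steps are rejected.
#'
#' @param ... Two or more steps, each a RInChI string, `rinchi_layers`, or
#'   [reaction_record()].  Addition is associative up to normalization.
#' @return A `rinchi_layers` object for the summed reaction (serialize with
#'   [build_rinchi()]).
#' @export
add_rinchis <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1]]) &&
      !inherits(steps[[1]], c("reaction_record", "rinchi_layers"))) {
    steps <- steps[[1]]
  }
  if (length(steps) < 2L) {
    stop_rxnid("add_rinchis() needs at least two steps",
               class = "rxnid_algebra_error")
  }
  recs <- lapply(steps, function(s) {
    if (inherits(s, "reaction_record")) s else layers_to_record(as_layers(s))
  })
  total <- Reduce(add_records, recs)
  assign_layers(normalize_record(total))
}

#' Compare two reactions by their hashed keys
#'
#' Reports equality at each key granularity and classifies the pair the way a
#' reaction-database deduplication pass would: reactions with equal Web keys
#' but different Short keys are the same chemistry with molecules assigned to
#' different roles (e.g. a solvent counted as reactant in one entry and agent
#' in the other).
#'
#' @param a,b [rinchi_keys()] bundles, or anything `rinchi_keys()` accepts.
#' @return A list of class `key_comparison` with logical fields `long_equal`,
#'   `short_equal`, `web_equal` and a `classification` of `"identical"`,
#'   `"same-chemistry-different-roles"` or `"distinct"`.
#' @export
compare_keys <- function(a, b) {
  if (!inherits(a, "key_bundle")) a <- rinchi_keys(a)
  if (!inherits(b, "key_bundle")) b <- rinchi_keys(b)
  long_equal <- identical(a$long, b$long)
  short_equal <- identical(a$short, b$short)
  web_equal <- identical(a$web, b$web)
  classification <- if (long_equal && short_equal && web_equal) {
    "identical"
  } else if (web_equal) {
    "same-chemistry-different-roles"
  } else {
    "distinct"
  }
  structure(list(long_equal = long_equal, short_equal = short_equal,
                 web_equal = web_equal, classification = classification),
            class = "key_comparison")
}

#' @export
print.key_comparison <- function(x, ...) {
  cat("<key_comparison>", x$classification, "\n")
  cat(sprintf("  long: %s  short: %s  web: %s\n",
              x$long_equal, x$short_equal, x$web_equal))
  invisible(x)
}
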