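# The six-layer RInChI string and the RAuxInfo string.
#
# Layer 1: version header "RInChI=1.00.1S".
# Layers 2/3: the two molecule groups, "!"-separated prefix-stripped InChIs,
#   sorted byte-wise; the group whose serialized string sorts first is always
#   layer 2, so the two layers are ordered alphabetically, not by role.
# Layer 4: agents.  Layer 5: direction flag /d+ /d- /d=.  Layer 6: /u counts
#   of no-structure components per layer.
# Separators with nothing to separate are omitted.

RINCHI_VERSION <- "1.00.1S"
RINCHI_PREFIX <- "RInChI=1.00.1S"
RAUX_PREFIX <- "RAuxInfo=1.00.1"

#' Serialize one molecule group
#'
#' Sorts prefix-stripped InChI bodies byte-wise and joins them with `"!"`.
#' The empty group serializes to the empty string (which sorts before any
#' non-empty group, fixing layer assignment for half-reactions).
#'
#' @param bodies Character vector of InChI bodies.
#' @return A single string.
#' @export
serialize_group <- function(bodies) {
  if (length(bodies) == 0L) return("")
  paste(ord_sort(bodies), collapse = "!")
}

new_rinchi_layers <- function(group_a, group_b, agents, direction, u) {
  stopifnot(is.data.frame(group_a), is.data.frame(group_b), is.data.frame(agents))
  u <- as.integer(u)
  stopifnot(length(u) == 3L, all(u >= 0L))
  structure(
    list(version = RINCHI_VERSION,
         group_a = group_a, group_b = group_b, agents = agents,
         direction = direction, u = u),
    class = "rinchi_layers"
  )
}

#' @export
print.rinchi_layers <- function(x, ...) {
  cat("<rinchi_layers>\n")
  cat("  layer 2:", nrow(x$group_a), "component(s)\n")
  cat("  layer 3:", nrow(x$group_b), "component(s)\n")
  cat("  layer 4:", nrow(x$agents), "component(s)\n")
  cat("  direction:", if (is.na(x$direction)) "unspecified" else x$direction,
      " u:", paste(x$u, collapse = "-"), "\n")
  invisible(x)
}

# Structured components of a group as a data.frame sorted by body.
group_frame <- function(comps) {
  structured <- Filter(function(c) !c$no_structure, comps)
  body <- vapply(structured, function(c) inchi_body(c$inchi), character(1))
  inchikey <- vapply(structured, function(c) c$inchikey %||% NA_character_,
                     character(1))
  auxinfo <- vapply(structured, function(c) c$auxinfo %||% NA_character_,
                    character(1))
  ord <- order(body, method = "radix")
  data.frame(body = body[ord], inchikey = inchikey[ord], auxinfo = auxinfo[ord],
             stringsAsFactors = FALSE)
}

count_nostructure <- function(comps) {
  sum(vapply(comps, function(c) isTRUE(c$no_structure), logical(1)))
}

#' Assign reaction groups to RInChI layers
#'
#' Serializes the reactant and product groups and makes the lexicographically
#' smaller serialized string layer two.  The direction flag records which
#' layer holds the starting materials: `"+"` if they landed in layer two,
#' `"-"` if in layer three, `"="` for an equilibrium, `NA` if unspecified.
#' No-structure counts travel with their groups through the swap.
#'
#' @param record A normalized [reaction_record()].
#' @return A `rinchi_layers` object.
#' @export
assign_layers <- function(record) {
  stopifnot(inherits(record, "reaction_record"))
  rf <- group_frame(record$reactants)
  pf <- group_frame(record$products)
  rs <- serialize_group(rf$body)
  ps <- serialize_group(pf$body)

  swapped <- ord_lt(ps, rs)  # products serialize first -> they are layer 2
  a <- if (swapped) pf else rf
  b <- if (swapped) rf else pf
  u_a <- if (swapped) count_nostructure(record$products) else count_nostructure(record$reactants)
  u_b <- if (swapped) count_nostructure(record$reactants) else count_nostructure(record$products)

  # "+" when the starting materials landed in layer 2, "-" when in layer 3
  direction <- switch(record$direction,
    equilibrium = "=",
    unspecified = NA_character_,
    forward = if (swapped) "-" else "+",
    backward = if (swapped) "+" else "-")

  new_rinchi_layers(a, b, group_frame(record$agents), direction,
                    c(u_a, u_b, count_nostructure(record$agents)))
}

#' Build the no-structure (sixth) layer
#'
#' @param u Integer triple: no-structure counts for layers two, three, four.
#' @return `"/u<a>-<b>-<c>"` with trailing zero sections dropped; the empty
#'   string when all counts are zero.
#' @examples
#' build_no_structure_layer(c(2, 3, 4))  # "/u2-3-4"
#' build_no_structure_layer(c(2, 3, 0))  # "/u2-3"
#' build_no_structure_layer(c(0, 0, 0))  # ""
#' @export
build_no_structure_layer <- function(u) {
  u <- as.integer(u)
  stopifnot(length(u) == 3L)
  if (any(is.na(u)) || any(u < 0L)) {
    stop_rxnid("no-structure counts must be non-negative integers",
               class = "rxnid_layer_error")
  }
  while (length(u) && u[length(u)] == 0L) u <- u[-length(u)]
  if (length(u) == 0L) return("")
  paste0("/u", paste(u, collapse = "-"))
}

# The "/L2<>L3<>L4" portion with trailing empty groups (and, if all groups
# are empty, the leading "/") omitted.
serialize_groups_part <- function(s2, s3, s4) {
  segs <- c(s2, s3, s4)
  while (length(segs) && !nzchar(segs[length(segs)])) segs <- segs[-length(segs)]
  if (length(segs) == 0L) return("")
  paste0("/", paste(segs, collapse = "<>"))
}

#' Build a RInChI string
#'
#' @param x A [reaction_record()] (normalized internally) or a
#'   `rinchi_layers` object from [assign_layers()] or [parse_rinchi()].
#' @return The RInChI as a single string.  A fully empty reaction with
#'   unspecified direction yields exactly `"RInChI=1.00.1S"`.
#' @examples
#' \dontrun{
#' build_rinchi(hydrolysis_example())
#' }
#' @export
build_rinchi <- function(x) {
  layers <- if (inherits(x, "reaction_record")) {
    assign_layers(normalize_record(x))
  } else if (inherits(x, "rinchi_layers")) {
    x
  } else {
    stop_rxnid("build_rinchi() expects a reaction_record or rinchi_layers",
               class = "rxnid_layer_error")
  }
  out <- paste0(
    RINCHI_PREFIX,
    serialize_groups_part(serialize_group(layers$group_a$body),
                          serialize_group(layers$group_b$body),
                          serialize_group(layers$agents$body))
  )
  if (!is.na(layers$direction)) out <- paste0(out, "/d", layers$direction)
  paste0(out, build_no_structure_layer(layers$u))
}

validate_group_bodies <- function(bodies, layer_name, strict) {
  if (length(bodies) <= 1L) return(bodies)
  srt <- ord_sort(bodies)
  if (anyDuplicated(bodies)) {
    i <- which(duplicated(bodies))[1]
    stop_rxnid("duplicated InChI body in ", layer_name, " at position ", i,
               ": ", bodies[i], class = "rxnid_parse_error")
  }
  if (!identical(srt, bodies)) {
    i <- which(srt != bodies)[1]
    if (strict) {
      stop_rxnid(layer_name, " is not alphabetically sorted (first violation ",
                 "at position ", i, ": ", bodies[i], ")",
                 class = "rxnid_parse_error")
    }
    bodies <- srt
  }
  bodies
}

#' Parse a RInChI string
#'
#' Inverse of [build_rinchi()]: recovers the molecule groups, the direction
#' flag and the no-structure counts.  `build_rinchi(parse_rinchi(s))`
#' reproduces `s` for every string `build_rinchi()` can emit.
#'
#' @param s A RInChI string beginning `"RInChI=1.00.1S"`.
#' @param strict If `TRUE` (default), unsorted or duplicated bodies within a
#'   layer are validation errors (reported with their positions); if `FALSE`,
#'   unsorted layers are re-sorted.
#' @return A `rinchi_layers` object (without InChIKeys or AuxInfo; these can
#'   be re-derived through the engine when needed).
#' @export
parse_rinchi <- function(s, strict = TRUE) {
  stopifnot(is_string(s))
  s <- trimws(s)
  if (!startsWith(s, "RInChI=")) {
    stop_rxnid("not a RInChI string: missing 'RInChI=' label",
               class = "rxnid_parse_error")
  }
  if (!startsWith(s, RINCHI_PREFIX)) {
    stop_rxnid("unknown RInChI version header: ",
               sub("/.*$", "", s), class = "rxnid_parse_error")
  }
  rest <- substr(s, nchar(RINCHI_PREFIX) + 1L, nchar(s))

  u <- c(0L, 0L, 0L)
  m <- regexpr("/u[0-9]+(-[0-9]+){0,2}$", rest)
  if (m > 0) {
    usec <- substr(rest, m + 2L, nchar(rest))
    vals <- as.integer(strsplit(usec, "-", fixed = TRUE)[[1]])
    u[seq_along(vals)] <- vals
    rest <- substr(rest, 1L, m - 1L)
  } else if (grepl("/u", rest, fixed = TRUE)) {
    stop_rxnid("malformed no-structure (/u) layer in: ", s,
               class = "rxnid_parse_error")
  }

  direction <- NA_character_
  dm <- regexpr("/d(.)$", rest)
  if (dm > 0) {
    dch <- substr(rest, dm + 2L, dm + 2L)
    dch <- chartr("−", "-", dch)  # accept the typographic minus
    if (!dch %in% c("+", "-", "=")) {
      stop_rxnid("malformed direction layer '/d", dch, "'",
                 class = "rxnid_parse_error")
    }
    direction <- dch
    rest <- substr(rest, 1L, dm - 1L)
  }

  groups <- list(character(0), character(0), character(0))
  if (nzchar(rest)) {
    if (!startsWith(rest, "/")) {
      stop_rxnid("malformed RInChI: expected '/' after the version header",
                 class = "rxnid_parse_error")
    }
    segs <- strsplit(substr(rest, 2L, nchar(rest)), "<>", fixed = TRUE)[[1]]
    # strsplit drops a trailing empty segment; "a<>" means an empty layer 3
    n_seps <- lengths(regmatches(rest, gregexpr("<>", rest, fixed = TRUE)))
    length(segs) <- n_seps + 1L
    segs[is.na(segs)] <- ""
    if (length(segs) > 3L) {
      stop_rxnid("too many '<>' separated groups (", length(segs), ")",
                 class = "rxnid_parse_error")
    }
    names_ <- c("layer 2", "layer 3", "layer 4")
    for (i in seq_along(segs)) {
      if (!nzchar(segs[i])) next
      bodies <- strsplit(segs[i], "!", fixed = TRUE)[[1]]
      if (any(!nzchar(bodies))) {
        stop_rxnid("empty component in ", names_[i], class = "rxnid_parse_error")
      }
      groups[[i]] <- validate_group_bodies(bodies, names_[i], strict)
    }
  }

  frame <- function(bodies) {
    data.frame(body = bodies,
               inchikey = rep(NA_character_, length(bodies)),
               auxinfo = rep(NA_character_, length(bodies)),
               stringsAsFactors = FALSE)
  }
  new_rinchi_layers(frame(groups[[1]]), frame(groups[[2]]), frame(groups[[3]]),
                    direction, u)
}

# ---- RAuxInfo ---------------------------------------------------------------

aux_body <- function(auxinfo) sub("^AuxInfo=[^/]*/", "", auxinfo)

#' Build a RAuxInfo string
#'
#' The RAuxInfo mirrors RInChI layers one to four and lists the per-component
#' InChI AuxInfo (atom numbering and original coordinates) in exactly the
#' component order of the RInChI, with the same separators.  It is what makes
#' reconstruction of an RXN file from a RInChI possible.  AuxInfo bodies are
#' stored with their `"AuxInfo=1/"` prefix stripped, mirroring the InChI
#' prefix rule; [parse_rauxinfo()] tolerates unstripped dialects.
#'
#' @param x A [reaction_record()] or `rinchi_layers` object whose structured
#'   components all carry engine AuxInfo.
#' @return The RAuxInfo as a single string.
#' @export
build_rauxinfo <- function(x) {
  layers <- if (inherits(x, "reaction_record")) {
    assign_layers(normalize_record(x))
  } else if (inherits(x, "rinchi_layers")) {
    x
  } else {
    stop_rxnid("build_rauxinfo() expects a reaction_record or rinchi_layers",
               class = "rxnid_layer_error")
  }
  ser <- function(df, layer_name) {
    if (nrow(df) == 0L) return("")
    if (anyNA(df$auxinfo)) {
      stop_rxnid("missing AuxInfo for a structured component in ", layer_name,
                 class = "rxnid_aux_error")
    }
    paste(aux_body(df$auxinfo), collapse = "!")
  }
  paste0(RAUX_PREFIX,
         serialize_groups_part(ser(layers$group_a, "layer 2"),
                               ser(layers$group_b, "layer 3"),
                               ser(layers$agents, "layer 4")))
}

#' Parse a RAuxInfo string
#'
#' @param s A string beginning `"RAuxInfo=1.00.1"`.
#' @return A list of three character vectors of AuxInfo bodies (layers two,
#'   three, four), prefix-stripped.
#' @export
parse_rauxinfo <- function(s) {
  stopifnot(is_string(s))
  s <- trimws(s)
  if (!startsWith(s, RAUX_PREFIX)) {
    stop_rxnid("unknown RAuxInfo header: ", sub("/.*$", "", s),
               class = "rxnid_parse_error")
  }
  rest <- substr(s, nchar(RAUX_PREFIX) + 1L, nchar(s))
  groups <- list(character(0), character(0), character(0))
  if (nzchar(rest)) {
    segs <- strsplit(substr(rest, 2L, nchar(rest)), "<>", fixed = TRUE)[[1]]
    n_seps <- lengths(regmatches(rest, gregexpr("<>", rest, fixed = TRUE)))
    length(segs) <- n_seps + 1L
    segs[is.na(segs)] <- ""
    if (length(segs) > 3L) {
      stop_rxnid("too many '<>' separated groups in RAuxInfo",
                 class = "rxnid_parse_error")
    }
    for (i in seq_along(segs)) {
      if (!nzchar(segs[i])) next
      pieces <- strsplit(segs[i], "!", fixed = TRUE)[[1]]
      groups[[i]] <- sub("^AuxInfo=[^/]*/", "", pieces)  # tolerate unstripped
    }
  }
  groups
}

#' Compute the RInChI of a reaction
#'
#' Convenience wrapper: normalizes the record and serializes it.  Equivalent
#' to `build_rinchi(x)`.
#'
#' @param x A [reaction_record()], or a path to / text of an RXN file.
#' @param direction Optional direction override applied when `x` is a file
#'   (RXN files cannot express equilibria or unknown directionality).
#' @return The RInChI string.
#' @export
rinchi <- function(x, direction = NULL) {
  if (is_string(x) && !inherits(x, "reaction_record")) x <- read_rxn(x)
  if (!is.null(direction)) x$direction <- match.arg(direction, rxnid_directions)
  build_rinchi(x)
}

#' Compute the RAuxInfo of a reaction
#'
#' @inheritParams rinchi
#' @return The RAuxInfo string.
#' @export
rauxinfo <- function(x, direction = NULL) {
  if (is_string(x) && !inherits(x, "reaction_record")) x <- read_rxn(x)
  if (!is.null(direction)) x$direction <- match.arg(direction, rxnid_directions)
  build_rauxinfo(x)
}
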