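# RXN / RD file reading and RXN reconstruction.
#
# The readers accept the MDL CTAB V2000 dialect.  RXN files carry starting
# materials and products; they cannot express equilibria, unknown
# directionality, or agents, so the reader defaults to a forward direction
# (overridable) and an empty agent group.  RD files additionally carry data
# fields; molfiles outside the RXN sections and datum molfiles whose field
# name contains CATALYST or SOLVENT (case-insensitive) are read as agents.
# Because standard RXN has no agent slot, write_rxn() appends agents behind a
# "$RXNID-AGENTS" comment sentinel, which read_rxn() recognizes; other
# readers ignore the trailing section.

AGENT_SENTINEL <- "$RXNID-AGENTS"

read_lines_or_text <- function(x) {
  stopifnot(is_string(x))
  if (!grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  strsplit(x, "\n", fixed = TRUE)[[1]]
}

# Extract the molfile block starting at `start` (the first header line).
# Returns list(molfile, next_line).
take_molfile <- function(lines, start) {
  end <- start + 3L
  while (end <= length(lines) && !grepl("^M  END", lines[end])) end <- end + 1L
  if (end > length(lines)) {
    stop_rxnid("truncated molfile block starting at line ", start,
               class = "rxnid_molfile_error")
  }
  molfile <- paste(lines[start:end], collapse = "\n")
  molfile_counts(molfile)  # validate
  list(molfile = molfile, next_line = end + 1L)
}

parse_rxn_counts <- function(line) {
  r <- suppressWarnings(as.integer(substr(line, 1, 3)))
  p <- suppressWarnings(as.integer(substr(line, 4, 6)))
  if (is.na(r) || is.na(p)) {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    r <- suppressWarnings(as.integer(tok[1]))
    p <- suppressWarnings(as.integer(tok[2]))
  }
  if (is.na(r) || is.na(p) || r < 0L || p < 0L) {
    stop_rxnid("unreadable RXN counts line: ", line, class = "rxnid_rxn_error")
  }
  c(reactants = r, products = p)
}

# Parse one $RXN section beginning at `start`.  Returns
# list(reactant_molfiles, product_molfiles, agent_molfiles, next_line).
parse_rxn_section <- function(lines, start) {
  if (!grepl("^\\$RXN", lines[start])) {
    stop_rxnid("expected '$RXN' at line ", start, class = "rxnid_rxn_error")
  }
  counts <- parse_rxn_counts(lines[start + 4L])
  pos <- start + 5L
  mols <- list()
  while (length(mols) < sum(counts)) {
    while (pos <= length(lines) && !grepl("^\\$MOL", lines[pos])) {
      if (grepl("^\\$(RXN|RFMT|DTYPE)", lines[pos]) ||
          startsWith(lines[pos], AGENT_SENTINEL)) break
      pos <- pos + 1L
    }
    if (pos > length(lines) || !grepl("^\\$MOL", lines[pos])) {
      stop_rxnid("RXN counts line declares ", sum(counts),
                 " molfiles but only ", length(mols), " were found",
                 class = "rxnid_rxn_error")
    }
    got <- take_molfile(lines, pos + 1L)
    mols <- c(mols, list(got$molfile))
    pos <- got$next_line
  }
  agents <- list()
  if (pos <= length(lines) && startsWith(lines[pos], AGENT_SENTINEL)) {
    pos <- pos + 1L
    while (pos <= length(lines) && grepl("^\\$MOL", lines[pos])) {
      got <- take_molfile(lines, pos + 1L)
      agents <- c(agents, list(got$molfile))
      pos <- got$next_line
    }
  }
  list(reactant_molfiles = mols[seq_len(counts[1])],
       product_molfiles = mols[counts[1] + seq_len(counts[2])],
       agent_molfiles = agents,
       next_line = pos)
}

#' Read an RXN file
#'
#' @param x Path to an RXN file, or its text.
#' @param direction Direction to record; RXN files cannot express equilibria
#'   or unknown directionality, so the default is `"forward"` and anything
#'   else must be supplied by the caller.
#' @return A [reaction_record()] with reactants and products in file order
#'   (not yet normalized).  Agents are populated only when the file carries
#'   the package's `$RXNID-AGENTS` trailing section.
#' @export
read_rxn <- function(x, direction = "forward") {
  lines <- read_lines_or_text(x)
  if (!length(lines) || !grepl("^\\$RXN", lines[1])) {
    stop_rxnid("not an RXN file: first line must start with '$RXN'",
               class = "rxnid_rxn_error")
  }
  sec <- parse_rxn_section(lines, 1L)
  reaction_record(reactants = sec$reactant_molfiles,
                  products = sec$product_molfiles,
                  agents = sec$agent_molfiles,
                  direction = direction)
}

#' Read an RD file
#'
#' Parses every `$RFMT` record.  Within a record, each embedded `$RXN` block
#' is one reaction step; a `$DTYPE`/`$DATUM` pair naming `VARIATION` before a
#' block assigns it to that variation (default 1).  Only variation 1 is used;
#' its steps are merged into a single record with the same set algebra as
#' [add_rinchis()], so intermediates produced by one step and consumed by the
#' next cancel.  Datum molfiles whose field name contains `CATALYST` or
#' `SOLVENT`, and molfiles outside any RXN section, become agents.  Malformed
#' datum blocks are skipped with a warning.
#'
#' @param x Path to an RD file, or its text.
#' @param direction Direction recorded on each merged record.
#' @return A list of [reaction_record()] objects, one per `$RFMT` entry.
#' @export
read_rdfile <- function(x, direction = "forward") {
  lines <- read_lines_or_text(x)
  if (!length(lines) || !grepl("^\\$RDFILE", lines[1])) {
    stop_rxnid("not an RD file: first line must start with '$RDFILE'",
               class = "rxnid_rd_error")
  }
  starts <- grep("^\\$RFMT", lines)
  if (!length(starts)) {
    stop_rxnid("RD file contains no '$RFMT' records", class = "rxnid_rd_error")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    records[[k]] <- parse_rd_record(lines[starts[k]:ends[k]], direction)
  }
  records
}

parse_rd_record <- function(lines, direction) {
  steps <- list()       # list of list(rxn = parsed section, variation = int)
  agents <- list()
  skipped <- 0L
  variation <- 1L
  pos <- 1L
  n <- length(lines)
  while (pos <= n) {
    line <- lines[pos]
    if (grepl("^\\$RXN", line)) {
      sec <- parse_rxn_section(lines, pos)
      steps <- c(steps, list(list(sec = sec, variation = variation)))
      variation <- 1L
      pos <- sec$next_line
    } else if (grepl("^\\$DTYPE", line)) {
      field <- trimws(sub("^\\$DTYPE", "", line))
      datum_at <- pos + 1L
      if (datum_at > n || !grepl("^\\$DATUM", lines[datum_at])) {
        warning("malformed datum block (no $DATUM) for field '", field,
                "'; skipped")
        skipped <- skipped + 1L
        pos <- pos + 1L
        next
      }
      value <- trimws(sub("^\\$DATUM", "", lines[datum_at]))
      if (grepl("VARIATION", toupper(field))) {
        v <- suppressWarnings(as.integer(value))
        if (!is.na(v) && v >= 1L) variation <- v
        pos <- datum_at + 1L
      } else if (grepl("CATALYST|SOLVENT", toupper(field))) {
        got <- tryCatch(take_molfile(lines, datum_at + 1L), error = function(e) NULL)
        if (is.null(got)) {
          warning("malformed molfile datum for field '", field, "'; skipped")
          skipped <- skipped + 1L
          pos <- datum_at + 1L
        } else {
          agents <- c(agents, list(got$molfile))
          pos <- got$next_line
        }
      } else {
        pos <- datum_at + 1L
      }
    } else if (grepl("^\\$MFMT", line)) {
      # a molecule outside any RXN section is an agent
      got <- tryCatch(take_molfile(lines, pos + 1L), error = function(e) NULL)
      if (is.null(got)) {
        warning("malformed molfile after $MFMT; skipped")
        skipped <- skipped + 1L
        pos <- pos + 1L
      } else {
        agents <- c(agents, list(got$molfile))
        pos <- got$next_line
      }
    } else {
      pos <- pos + 1L
    }
  }

  keep <- Filter(function(s) s$variation == 1L, steps)
  if (!length(keep)) {
    record <- reaction_record(agents = agents, direction = direction)
  } else {
    recs <- lapply(keep, function(s) {
      reaction_record(reactants = s$sec$reactant_molfiles,
                      products = s$sec$product_molfiles,
                      agents = s$sec$agent_molfiles,
                      direction = direction)
    })
    record <- Reduce(add_records, recs)
    record$agents <- dedupe_group(c(record$agents, as_component_list(agents)))
    record$direction <- direction
  }
  attr(record, "skipped_datum_blocks") <- skipped
  record
}

# ---- RXN reconstruction -----------------------------------------------------

# Overlay the original 2D coordinates (AuxInfo /N numbering + /rC coordinate
# list) onto a molfile rebuilt from the bare InChI.
overlay_aux_coords <- function(molfile, aux) {
  nmatch <- regmatches(aux, regexpr("/N:[0-9,;]+", aux))
  cmatch <- regmatches(aux, regexpr("/rC:[^/]*", aux))
  if (!length(nmatch) || !length(cmatch)) return(molfile)
  numbering <- as.integer(strsplit(sub("^/N:", "", nmatch), "[,;]")[[1]])
  coords <- strsplit(sub("^/rC:", "", cmatch), ";", fixed = TRUE)[[1]]
  parse_xyz <- function(s) {
    if (!nzchar(s)) return(c(0, 0, 0))
    v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
    v[is.na(v)] <- 0
    c(v, 0, 0, 0)[1:3]
  }
  lines <- strsplit(molfile, "\n", fixed = TRUE)[[1]]
  natoms <- molfile_counts(molfile)$natoms
  if (natoms != length(numbering) || max(numbering) > length(coords)) {
    return(molfile)  # atom sets disagree (e.g. explicit H); keep engine coords
  }
  for (k in seq_len(natoms)) {
    xyz <- parse_xyz(coords[numbering[k]])
    line <- lines[4L + k]
    lines[4L + k] <- paste0(sprintf("%10.4f%10.4f%10.4f", xyz[1], xyz[2], xyz[3]),
                            substr(line, 31L, nchar(line)))
  }
  paste(lines, collapse = "\n")
}

#' Reconstruct an RXN file from a RInChI and its RAuxInfo
#'
#' Rebuilds each component molfile from its InChI through the engine and
#' restores the original atom layout from the aligned AuxInfo.  Without
#' RAuxInfo the reconstruction is refused: third-party layout software would
#' be needed to invent coordinates.
#'
#' Layer-two components are written as reactants when the direction flag is
#' `"+"` (swapped for `"-"`); an equilibrium or unspecified direction is
#' emitted in forward order with a comment line noting the lost
#' directionality.  Agents are appended behind the `$RXNID-AGENTS` sentinel.
#'
#' @param x A RInChI string or `rinchi_layers` object.
#' @param rauxinfo The matching RAuxInfo string (or parsed list from
#'   [parse_rauxinfo()]).
#' @param path Optional path to write the RXN text to.
#' @return The RXN text, invisibly when `path` is given.
#' @export
write_rxn <- function(x, rauxinfo = NULL, path = NULL) {
  layers <- as_layers(x)
  if (is.null(rauxinfo)) {
    stop_rxnid("RAuxInfo is required to rebuild an RXN file; without it, ",
               "third-party software would be needed to generate coordinates",
               class = "rxnid_aux_error")
  }
  aux <- if (is.list(rauxinfo)) rauxinfo else parse_rauxinfo(rauxinfo)
  sizes <- c(nrow(layers$group_a), nrow(layers$group_b), nrow(layers$agents))
  if (!identical(lengths(aux), as.integer(sizes))) {
    stop_rxnid("RAuxInfo component counts (", paste(lengths(aux), collapse = "/"),
               ") do not match the RInChI layers (", paste(sizes, collapse = "/"),
               ")", class = "rxnid_aux_error")
  }
  rebuild <- function(df, aux_bodies) {
    lapply(seq_len(nrow(df)), function(i) {
      mol <- molfile_from_inchi(inchi_unbody(df$body[i]))
      # stereo components keep the engine's wedge-consistent layout: moving
      # atoms to the AuxInfo coordinates would invalidate the wedge geometry
      if (nzchar(decompose_inchi(df$body[i])$minor)) return(mol)
      overlay_aux_coords(mol, aux_bodies[i])
    })
  }
  mols_a <- rebuild(layers$group_a, aux[[1]])
  mols_b <- rebuild(layers$group_b, aux[[2]])
  mols_g <- rebuild(layers$agents, aux[[3]])

  swapped <- identical(layers$direction, "-")
  reactants <- if (swapped) mols_b else mols_a
  products <- if (swapped) mols_a else mols_b
  comment <- if (is.na(layers$direction)) {
    "direction unspecified in source RInChI"
  } else if (layers$direction == "=") {
    "equilibrium direction not representable in RXN; emitted forward"
  } else ""

  out <- c("$RXN", "", "rxnid", comment,
           sprintf("%3d%3d", length(reactants), length(products)))
  for (m in c(reactants, products)) out <- c(out, "$MOL", m)
  if (length(mols_g)) {
    out <- c(out, AGENT_SENTINEL)
    for (m in mols_g) out <- c(out, "$MOL", m)
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Batch-process reaction files into a table
#'
#' @param files Character vector of RXN / RD file paths.
#' @param direction Direction recorded for every file (see [read_rxn()]).
#' @return A tibble with one row per reaction: `file`, `rinchi`, `rauxinfo`,
#'   `long_key`, `short_key`, `web_key`.
#' @export
rinchi_table <- function(files, direction = "forward") {
  records <- list()
  src <- character(0)
  for (f in files) {
    first <- readLines(f, n = 1L, warn = FALSE)
    if (length(first) && grepl("^\\$RDFILE", first)) {
      recs <- read_rdfile(f, direction = direction)
    } else {
      recs <- list(read_rxn(f, direction = direction))
    }
    records <- c(records, recs)
    src <- c(src, rep(f, length(recs)))
  }
  rows <- lapply(records, function(r) {
    layers <- assign_layers(normalize_record(r))
    keys <- rinchi_keys(layers)
    tibble::tibble(rinchi = build_rinchi(layers),
                   rauxinfo = build_rauxinfo(layers),
                   long_key = keys$long, short_key = keys$short,
                   web_key = keys$web)
  })
  out <- do.call(rbind, rows)
  tibble::add_column(out, file = src, .before = 1L)
}
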