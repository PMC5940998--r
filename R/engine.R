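# Boundary to the external standard-InChI engine.
#
# All structure-level identifiers (InChI, AuxInfo, InChIKey) are produced by
# the InChI library bundled with Open Babel, driven through the `obabel`
# command-line tool.  The package never re-implements any part of InChI
# canonicalization; it only validates molfile blocks, batches them through the
# engine, and caches results per molfile text so repeated components (common
# in fixture sets) cost a single engine call.

the <- new.env(parent = emptyenv())
the$identity_cache <- new.env(parent = emptyenv())
the$engine_version <- NULL

#' Is the InChI engine available?
#'
#' The package delegates InChI/AuxInfo/InChIKey generation to Open Babel's
#' bundled standard-InChI library via the `obabel` executable.
#'
#' @return `TRUE` if `obabel` is found on the `PATH`.
#' @export
inchi_engine_available <- function() {
  nzchar(Sys.which("obabel"))
}

#' Version string of the InChI engine
#'
#' @return A single string such as `"Open Babel 3.1.1"`, recorded once per
#'   session.  All identities produced in one session carry this engine tag,
#'   so mixed-version reactions cannot arise in-process.
#' @export
inchi_engine_version <- function() {
  if (is.null(the$engine_version)) {
    require_engine()
    out <- suppressWarnings(system2("obabel", "-V", stdout = TRUE, stderr = FALSE))
    the$engine_version <- trimws(sub("--.*$", "", out[1]))
  }
  the$engine_version
}

require_engine <- function() {
  if (!inchi_engine_available()) {
    stop_rxnid(
      "the 'obabel' executable was not found on the PATH; ",
      "Open Babel is required for InChI generation",
      class = "rxnid_engine_error"
    )
  }
}

# ---- molfile validation -----------------------------------------------------

# Parse and validate the counts line of a V2000 molfile block.  Returns a
# list(natoms, nbonds) or raises for syntactically corrupt blocks.  A molfile
# with zero atoms is *valid* and denotes a no-structure component.
molfile_counts <- function(molfile) {
  lines <- strsplit(molfile, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) {
    stop_rxnid("corrupt molfile: fewer than 4 lines", class = "rxnid_molfile_error")
  }
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    stop_rxnid("V3000 connection tables are not supported", class = "rxnid_molfile_error")
  }
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms)) {
    # be lenient about column alignment: fall back to whitespace tokens
    tok <- strsplit(trimws(counts), "[[:space:]]+")[[1]]
    natoms <- suppressWarnings(as.integer(tok[1]))
    nbonds <- suppressWarnings(as.integer(tok[2]))
  }
  if (is.na(natoms) || natoms < 0L) {
    stop_rxnid("corrupt molfile: unreadable counts line: ", counts,
               class = "rxnid_molfile_error")
  }
  if (is.na(nbonds)) nbonds <- 0L
  if (!any(grepl("^M  END", lines))) {
    stop_rxnid("corrupt molfile: missing 'M  END'", class = "rxnid_molfile_error")
  }
  if (length(lines) < 4L + natoms + nbonds) {
    stop_rxnid("corrupt molfile: counts line declares ", natoms, " atoms / ",
               nbonds, " bonds but the block is too short",
               class = "rxnid_molfile_error")
  }
  list(natoms = natoms, nbonds = nbonds)
}

# ---- batched engine calls ---------------------------------------------------

# Tag each molfile with a synthetic title (line 1) so engine output can be
# re-aligned even when the engine silently skips a block.
retitle_molfile <- function(molfile, title) {
  lines <- strsplit(molfile, "\n", fixed = TRUE)[[1]]
  lines[1] <- title
  paste(lines, collapse = "\n")
}

obabel_batch <- function(molfiles, out_args) {
  tagged <- vapply(seq_along(molfiles),
                   function(i) retitle_molfile(molfiles[[i]], sprintf("rxnid%06d", i)),
                   character(1))
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(sdf), add = TRUE)
  writeLines(paste0(paste(tagged, collapse = "\n$$$$\n"), "\n$$$$"), sdf)
  suppressWarnings(system2("obabel", c(sdf, out_args), stdout = TRUE, stderr = FALSE))
}

# Run the uncached molfiles through the engine.  Returns a list (parallel to
# `molfiles`) of list(inchi, auxinfo, inchikey); entries the engine could not
# convert are all-NA.
engine_identify <- function(molfiles) {
  require_engine()
  n <- length(molfiles)
  res <- replicate(n, list(inchi = NA_character_, auxinfo = NA_character_,
                           inchikey = NA_character_), simplify = FALSE)
  if (n == 0L) return(res)

  out <- obabel_batch(molfiles, c("-oinchi", "-xa", "-xt"))
  idx <- NA_integer_
  for (line in out) {
    if (startsWith(line, "InChI=")) {
      sp <- regexpr(" ", line, fixed = TRUE)
      if (sp > 0) {
        title <- substr(line, sp + 1L, nchar(line))
        idx <- suppressWarnings(as.integer(sub("^rxnid", "", trimws(title))))
        if (!is.na(idx)) res[[idx]]$inchi <- substr(line, 1L, sp - 1L)
      }
    } else if (startsWith(line, "AuxInfo=") && !is.na(idx)) {
      res[[idx]]$auxinfo <- line
      idx <- NA_integer_
    }
  }

  keys <- obabel_batch(molfiles, c("-oinchi", "-xK", "-xt"))
  for (line in keys) {
    sp <- regexpr(" ", line, fixed = TRUE)
    if (sp > 0) {
      key <- substr(line, 1L, sp - 1L)
      i <- suppressWarnings(as.integer(sub("^rxnid", "",
                                           trimws(substr(line, sp + 1L, nchar(line))))))
      if (!is.na(i) && grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)) {
        res[[i]]$inchikey <- key
      }
    }
  }
  res
}

# Cached identity lookup for a character vector of molfile blocks.
identify_molfiles <- function(molfiles) {
  molfiles <- as.character(molfiles)
  keys <- if (length(molfiles)) as.character(openssl::md5(molfiles)) else character(0)
  need <- which(!vapply(keys, exists, logical(1), envir = the$identity_cache))
  need <- need[!duplicated(keys[need])]
  if (length(need)) {
    # zero-atom blocks never reach the engine: they are valid no-structures
    natoms <- vapply(molfiles[need], function(m) molfile_counts(m)$natoms, integer(1))
    run <- need[natoms > 0L]
    for (i in need[natoms == 0L]) {
      assign(keys[i], list(inchi = NA_character_, auxinfo = NA_character_,
                           inchikey = NA_character_), envir = the$identity_cache)
    }
    if (length(run)) {
      got <- engine_identify(molfiles[run])
      for (j in seq_along(run)) {
        assign(keys[run[j]], got[[j]], envir = the$identity_cache)
      }
    }
  }
  lapply(keys, get, envir = the$identity_cache)
}

# Engine route from a bare standard InChI string to its InChIKey (used when
# layers are reconstructed from a parsed RInChI that carries no keys).
inchikey_from_inchi <- function(inchis) {
  require_engine()
  if (length(inchis) == 0L) return(character(0))
  inf <- tempfile(fileext = ".inchi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(inchis, inf)
  out <- suppressWarnings(system2("obabel", c(inf, "-iinchi", "-oinchi", "-xK"),
                                  stdout = TRUE, stderr = FALSE))
  out <- out[grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", out)]
  if (length(out) != length(inchis)) {
    stop_rxnid("the engine failed to derive an InChIKey for ",
               length(inchis) - length(out), " InChI string(s)",
               class = "rxnid_engine_error")
  }
  out
}

# Engine route from a bare standard InChI to a V2000 molfile block.  2D
# coordinates are generated so that wedge bonds carry any stereochemistry;
# for achiral components the layout is later replaced from AuxInfo.
molfile_from_inchi <- function(inchi) {
  require_engine()
  inf <- tempfile(fileext = ".inchi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(inchi, inf)
  out <- suppressWarnings(system2("obabel", c(inf, "-iinchi", "-osdf", "--gen2d"),
                                  stdout = TRUE, stderr = FALSE))
  if (!any(grepl("^M  END", out))) {
    stop_rxnid("the engine could not rebuild a structure from: ", inchi,
               class = "rxnid_engine_error")
  }
  paste(out[seq_len(max(grep("^M  END", out)))], collapse = "\n")
}

#' Derive the InChI identity of one molfile
#'
#' Runs a single MDL V2000 molfile block through the standard-InChI engine and
#' returns a structure component holding the InChI, AuxInfo and InChIKey.  A
#' syntactically valid block with zero atoms (or one the engine cannot convert)
#' yields a no-structure component; a corrupt block raises an error.
#'
#' @param molfile A single string containing a V2000 connection-table block
#'   (up to and including `M  END`).
#' @return A `structure_component` object.
#' @examples
#' \dontrun{
#' comp <- molfile_to_identity(example_molfile("ethanol"))
#' comp$inchi     # "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3"
#' comp$inchikey  # "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"
#' }
#' @export
molfile_to_identity <- function(molfile) {
  stopifnot(is_string(molfile))
  molfile_counts(molfile)  # validate; raises on corrupt blocks
  id <- identify_molfiles(molfile)[[1]]
  structure_component(
    molfile = molfile,
    inchi = if (is.na(id$inchi)) NULL else id$inchi,
    auxinfo = if (is.na(id$auxinfo)) NULL else id$auxinfo,
    inchikey = if (is.na(id$inchikey)) NULL else id$inchikey
  )
}
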