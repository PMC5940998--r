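# InChI string surgery: prefix stripping and the major/minor/proton split.
#
# A standard InChI body is a "/"-separated sequence of sublayers in a fixed
# order: formula, /c (connections), /h (hydrogens), /q (charge), /p (proton
# balance), then stereo (/b /t /m /s) and isotopic (/i ...) sublayers.  The
# hashed reaction keys split each component into a *major* part (formula, /c,
# /h, /q), a signed *proton count* (/p), and a *minor* part (everything
# after), mirroring the first/second-block partition of the InChIKey.

#' Strip the standard InChI prefix
#'
#' RInChI layers list InChIs with the common `"InChI=1S/"` prefix removed,
#' since the version is already recorded in layer one.  Non-standard InChIs
#' (any other prefix) are rejected.
#'
#' @param inchi A standard InChI string.
#' @return The InChI body (everything after `"InChI=1S/"`).
#' @examples
#' inchi_body("InChI=1S/H2O/h1H2")  # "H2O/h1H2"
#' @export
inchi_body <- function(inchi) {
  stopifnot(is.character(inchi))
  bad <- !startsWith(inchi, "InChI=1S/")
  if (any(bad)) {
    stop_rxnid("not a standard (1S) InChI: ", inchi[bad][1],
               class = "rxnid_inchi_error")
  }
  substr(inchi, 10L, nchar(inchi))
}

#' Re-attach the standard InChI prefix
#'
#' Exact inverse of [inchi_body()].
#'
#' @param body An InChI body string.
#' @return The full standard InChI.
#' @export
inchi_unbody <- function(body) paste0("InChI=1S/", body)

#' Split an InChI into major, minor and proton parts
#'
#' @param inchi A standard InChI string *or* a prefix-stripped body.
#' @return A list with elements `body`, `major` (formula plus `/c`, `/h`, `/q`
#'   sublayers), `minor` (all later sublayers, each with its leading slash,
#'   excluding `/p`), and `protons` (the signed integer total of the `/p`
#'   sublayer, 0 if absent).  Concatenating `major`, the `/p` sublayer and
#'   `minor` in original order reproduces `body`.
#' @examples
#' decompose_inchi("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")
#' @export
decompose_inchi <- function(inchi) {
  stopifnot(is_string(inchi))
  body <- if (startsWith(inchi, "InChI=")) inchi_body(inchi) else inchi
  tokens <- strsplit(body, "/", fixed = TRUE)[[1]]
  major <- tokens[1]  # molecular formula, always present
  minor <- character(0)
  protons <- 0L
  in_major <- TRUE
  for (tok in tokens[-1]) {
    tag <- substr(tok, 1, 1)
    if (tag == "p") {
      # "/p-1", or ";"-separated per-component totals in composite InChIs
      protons <- protons +
        sum(as.integer(regmatches(tok, gregexpr("[+-]?[0-9]+", tok))[[1]]))
      in_major <- FALSE  # /p closes the charge block
    } else if (in_major && tag %in% c("c", "h", "q")) {
      major <- paste0(major, "/", tok)
    } else {
      in_major <- FALSE
      minor <- c(minor, paste0("/", tok))
    }
  }
  list(body = body, major = major, minor = paste(minor, collapse = ""),
       protons = protons)
}
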