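# Hashed reaction keys: Long-, Short- and Web-RInChIKey.
#
# The hash primitive is SHA-256 truncated and rendered as uppercase letters
# with the InChIKey base-26 encoding: the digest is read as consecutive
# little-endian bit windows encoded as letter triplets (14 bits each) with a
# letter doublet (9 bits) after the fourth triplet, exactly as the InChIKey
# encodes its own hash blocks.  The triplet code maps 0..16383 onto the
# alphabetically ordered three-letter strings, skipping the 676 starting with
# "E" and the 516 from "TAA" to "TTV"; the doublet code maps 0..511 onto the
# first 512 two-letter strings.  This reproduces the published blank strings
# "UHFF" and "UHFFFADPSC" for the empty payload and the printed worked-example
# key hashes.
#
# Payload convention (calibrated against the same anchors): the per-component
# major (or minor) strings are joined with "!" in RInChI component order,
# empty pieces dropped; an empty set hashes the empty payload.

base26_triplet <- function(v) {
  # skip the excluded blocks of the alphabetical triplet list
  v <- v + ifelse(v >= 2704L, 676L, 0L)          # "E??" block
  v <- v + ifelse(v >= 12844L, 516L, 0L)         # "TAA".."TTV"
  paste0(LETTERS[v %/% 676L + 1L],
         LETTERS[(v %/% 26L) %% 26L + 1L],
         LETTERS[v %% 26L + 1L])
}

base26_doublet <- function(v) {
  paste0(LETTERS[v %/% 26L + 1L], LETTERS[v %% 26L + 1L])
}

#' Hash a payload into uppercase letters
#'
#' The key-hashing primitive: SHA-256 of the payload, rendered as letters via
#' the InChIKey base-26 encoding and truncated to `n` characters.  Equal
#' payloads give equal outputs; the empty payload yields the canonical blank
#' strings (`"UHFF"` at 4 letters, `"UHFFFADPSC"` at 10).
#'
#' @param payload A single string (may be empty).
#' @param n Output length in letters: 4, 10, 12 or 17.
#' @return A string of `n` uppercase letters.
#' @examples
#' hash_letters("", 10)  # "UHFFFADPSC"
#' hash_letters("", 4)   # "UHFF"
#' @export
hash_letters <- function(payload, n) {
  stopifnot(is_string(payload))
  if (!n %in% c(4L, 10L, 12L, 17L)) {
    stop_rxnid("unsupported hash length: ", n, " (expected 4, 10, 12 or 17)",
               class = "rxnid_key_error")
  }
  d <- as.integer(openssl::sha256(charToRaw(payload)))
  stream <- paste0(
    base26_triplet(d[1] + (d[2] %% 64L) * 256L),                    # bits 0-13
    base26_triplet(d[2] %/% 64L + d[3] * 4L + (d[4] %% 16L) * 1024L),  # 14-27
    base26_triplet(d[4] %/% 16L + d[5] * 16L + (d[6] %% 4L) * 4096L),  # 28-41
    base26_triplet(d[6] %/% 4L + d[7] * 64L),                       # bits 42-55
    base26_doublet(d[8] + (d[9] %% 2L) * 256L),                     # bits 56-64
    base26_triplet(d[9] + (d[10] %% 64L) * 256L)                    # bits 64-77
  )
  substr(stream, 1L, n)
}

#' Direction letter of the RInChIKey header
#'
#' Maps the layer-five flag to the key alphabet: Forward, Backward,
#' Equilibrium, Undefined.
#'
#' @param direction `"+"`, `"-"`, `"="` or `NA`.
#' @return `"F"`, `"B"`, `"E"` or `"U"`.
#' @export
direction_letter <- function(direction) {
  if (is.null(direction) || is.na(direction)) return("U")
  switch(direction, "+" = "F", "-" = "B", "=" = "E",
         stop_rxnid("unknown direction flag: ", direction,
                    class = "rxnid_key_error"))
}

#' Protonation letter
#'
#' Encodes a summed proton balance as a single letter: `"N"` for zero,
#' stepping back for negative (`"M"` is -1) and forward for positive (`"O"`
#' is +1).  Balances beyond the A..Z range saturate with a warning.
#'
#' @param p Signed integer proton balance.
#' @return A single uppercase letter.
#' @export
protonation_letter <- function(p) {
  p <- as.integer(p)
  code <- utf8ToInt("N") + p
  if (code < utf8ToInt("A") || code > utf8ToInt("Z")) {
    warning("proton balance ", p, " outside the encodable range; saturating")
    code <- max(utf8ToInt("A"), min(utf8ToInt("Z"), code))
  }
  intToUtf8(code)
}

#' No-structure count letter
#'
#' `"Z"` encodes zero no-structure components, `"A"` one, `"B"` two, and so
#' on.  Counts of 25 or more saturate at `"Y"` (never colliding with the zero
#' letter) with a warning.
#'
#' @param count Non-negative integer.
#' @return A single uppercase letter.
#' @export
nostructure_letter <- function(count) {
  count <- as.integer(count)
  stopifnot(count >= 0L)
  if (count == 0L) return("Z")
  if (count > 25L) {
    warning("no-structure count ", count, " saturates the letter code at 'Y'")
    count <- 25L
  }
  LETTERS[count]
}

# ---- payload assembly -------------------------------------------------------

decompose_bodies <- function(bodies) {
  if (length(bodies) == 0L) {
    return(list(major = character(0), minor = character(0), protons = integer(0)))
  }
  dec <- lapply(bodies, decompose_inchi)
  list(major = vapply(dec, `[[`, character(1), "major"),
       minor = vapply(dec, `[[`, character(1), "minor"),
       protons = vapply(dec, `[[`, integer(1), "protons"))
}

join_payload <- function(pieces) {
  pieces <- pieces[nzchar(pieces)]
  paste(pieces, collapse = "!")
}

as_layers <- function(x) {
  if (inherits(x, "rinchi_layers")) return(x)
  if (inherits(x, "reaction_record")) return(assign_layers(normalize_record(x)))
  if (is_string(x) && startsWith(x, "RInChI=")) return(parse_rinchi(x))
  stop_rxnid("expected a reaction_record, rinchi_layers, or RInChI string",
             class = "rxnid_key_error")
}

# ---- the three keys ---------------------------------------------------------

#' Long-RInChIKey
#'
#' Lists every structured component by its standard InChIKey, in RInChI
#' component order, single-hyphen-joined within a layer and double-hyphen
#' separated between layers two, three and four.  The header `"SA"` marks the
#' standard InChI flavour, followed by the direction letter and the unused
#' filler `"UHFF"`.  No-structure components carry no InChIKey and are not
#' listed (they remain visible in the RInChI's sixth layer).
#'
#' @param x A [reaction_record()], `rinchi_layers`, or RInChI string.  When
#'   component InChIKeys are absent (e.g. after [parse_rinchi()]) they are
#'   re-derived from the InChIs through the engine.
#' @return The labelled key string.
#' @export
long_key <- function(x) {
  layers <- backfill_inchikeys(as_layers(x))
  seg <- function(df) {
    if (nrow(df) == 0L) return("")
    if (anyNA(df$inchikey)) {
      stop_rxnid("a structured component lacks an InChIKey",
                 class = "rxnid_key_error")
    }
    paste(df$inchikey, collapse = "-")
  }
  paste0("Long-RInChIKey=SA-", direction_letter(layers$direction), "UHFF-",
         seg(layers$group_a), "--", seg(layers$group_b), "--",
         seg(layers$agents))
}

backfill_inchikeys <- function(layers) {
  for (g in c("group_a", "group_b", "agents")) {
    df <- layers[[g]]
    miss <- which(is.na(df$inchikey))
    if (length(miss)) {
      df$inchikey[miss] <- inchikey_from_inchi(inchi_unbody(df$body[miss]))
      layers[[g]] <- df
    }
  }
  layers
}

#' Short-RInChIKey
#'
#' The fixed-length key: 55 letters in nine hyphen-separated groups (63
#' characters in all).  After the `"SA"` header and the direction group come
#' three ten-letter hashes of the concatenated major InChI layers of RInChI
#' layers two, three and four; then three five-letter groups, each a
#' protonation letter followed by a four-letter hash of the concatenated
#' minor layers; and finally three letters counting no-structure components
#' per layer.  Empty layers hash to the blank strings (`"UHFFFADPSC"`,
#' `"UHFF"`).  There is no check digit.
#'
#' @inheritParams long_key
#' @return The labelled key string.
#' @export
short_key <- function(x) {
  layers <- as_layers(x)
  dir <- direction_letter(layers$direction)
  dec <- lapply(list(layers$group_a, layers$group_b, layers$agents),
                function(df) decompose_bodies(df$body))
  majors <- vapply(dec, function(d) hash_letters(join_payload(d$major), 10L),
                   character(1))
  minors <- vapply(dec, function(d) {
    paste0(protonation_letter(sum(d$protons)),
           hash_letters(join_payload(d$minor), 4L))
  }, character(1))
  nostr <- paste(vapply(layers$u, nostructure_letter, character(1)),
                 collapse = "")
  paste0("Short-RInChIKey=",
         paste(c("SA", paste0(dir, "UHFF"), majors, minors, nostr),
               collapse = "-"))
}

#' Web-RInChIKey
#'
#' The role-insensitive key: all structured components from layers two, three
#' and four are pooled, deduplicated and sorted, so moving a molecule between
#' reactants, products and agents does not change the key.  The body is a
#' seventeen-letter hash of the pooled major layers, a hyphen, the total
#' protonation letter, a twelve-letter hash of the pooled minor layers, and
#' the `"SA"` flavour marker -- 47 characters in all including the label.
#'
#' @inheritParams long_key
#' @return The labelled key string.
#' @export
web_key <- function(x) {
  layers <- as_layers(x)
  pool <- ord_sort(unique(c(layers$group_a$body, layers$group_b$body,
                            layers$agents$body)))
  dec <- decompose_bodies(pool)
  paste0("Web-RInChIKey=",
         hash_letters(join_payload(dec$major), 17L), "-",
         protonation_letter(sum(dec$protons)),
         hash_letters(join_payload(dec$minor), 12L), "SA")
}

#' All three RInChIKeys of a reaction
#'
#' @inheritParams long_key
#' @param bare If `TRUE`, strip the `"Long-RInChIKey="` style labels.
#' @return A list of class `key_bundle` with elements `long`, `short`, `web`.
#' @examples
#' \dontrun{
#' rinchi_keys(hydrolysis_example())
#' }
#' @export
rinchi_keys <- function(x, bare = FALSE) {
  layers <- as_layers(x)
  keys <- list(long = long_key(layers), short = short_key(layers),
               web = web_key(layers))
  if (bare) keys <- lapply(keys, function(k) sub("^[A-Za-z-]+RInChIKey=", "", k))
  structure(keys, class = "key_bundle")
}

#' @export
print.key_bundle <- function(x, ...) {
  cat(x$long, x$short, x$web, sep = "\n")
  invisible(x)
}
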