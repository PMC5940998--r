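# Shared fixtures and independent oracles used across the suite.

# Published reference values for the ethyl acetate hydrolysis example.
REF <- list(
  inchi = c(
    "ethyl acetate" = "InChI=1S/C4H8O2/c1-3-6-4(2)5/h3H2,1-2H3",
    "water" = "InChI=1S/H2O/h1H2",
    "sulfuric acid" = "InChI=1S/H2O4S/c1-5(2,3)4/h(H2,1,2,3,4)",
    "acetic acid" = "InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)",
    "ethanol" = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3"
  ),
  inchikey = c(
    "ethyl acetate" = "XEKOWRVHYACXOJ-UHFFFAOYSA-N",
    "water" = "XLYOFNOQVPJJNP-UHFFFAOYSA-N",
    "sulfuric acid" = "QAOWNCQODCNURD-UHFFFAOYSA-N",
    "acetic acid" = "QTBSBXVTEAMEQO-UHFFFAOYSA-N",
    "ethanol" = "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"
  ),
  rinchi = paste0(
    "RInChI=1.00.1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)!C2H6O/c1-2-3/h3H,2H2,1H3",
    "<>C4H8O2/c1-3-6-4(2)5/h3H2,1-2H3!H2O/h1H2",
    "<>H2O4S/c1-5(2,3)4/h(H2,1,2,3,4)/d="
  ),
  web_key = "Web-RInChIKey=SMUHAWIQPXIVCEVKG-NUHFFFADPSCTJSA",
  short_l2_hash = "JJFIATRHOH"
)

# Lightweight components carrying only an InChI (no engine involved); handy
# for model-level and algebra-level tests.
sc <- function(body) structure_component(inchi = paste0("InChI=1S/", body))

rec_bodies <- function(record, group) {
  vapply(Filter(function(c) !c$no_structure, record[[group]]),
         function(c) c$inchi, character(1))
}

# ---- independent re-implementation of the letter-hash primitive -------------
# Builds the triplet/doublet code tables by explicit filtering of the sorted
# letter strings and extracts digest bits via rawToBits(); shares no code
# with hash_letters().
oracle_tables <- local({
  g <- expand.grid(a = LETTERS, b = LETTERS, c = LETTERS,
                   stringsAsFactors = FALSE)
  trip <- sort(paste0(g$a, g$b, g$c), method = "radix")
  trip <- trip[substr(trip, 1, 1) != "E"]
  trip <- trip[!(trip >= "TAA" & trip <= "TTV")]
  d <- expand.grid(a = LETTERS, b = LETTERS, stringsAsFactors = FALSE)
  dou <- sort(paste0(d$a, d$b), method = "radix")[1:512]
  list(trip = trip, dou = dou)
})

oracle_hash_letters <- function(payload, n) {
  bits <- as.integer(rawToBits(openssl::sha256(charToRaw(payload))))
  window <- function(start, width) {
    sum(bits[(start + 1):(start + width)] * 2^(0:(width - 1)))
  }
  stream <- paste0(
    oracle_tables$trip[window(0, 14) + 1],
    oracle_tables$trip[window(14, 14) + 1],
    oracle_tables$trip[window(28, 14) + 1],
    oracle_tables$trip[window(42, 14) + 1],
    oracle_tables$dou[window(56, 9) + 1],
    oracle_tables$trip[window(64, 14) + 1]
  )
  substr(stream, 1, n)
}

# Independent RInChI writer (Open Babel's own plugin), usable as an oracle
# for agent-free forward reactions.
obabel_rinchi <- function(rxn_text) {
  f <- tempfile(fileext = ".rxn")
  on.exit(unlink(f))
  writeLines(rxn_text, f, sep = "")
  out <- suppressWarnings(system2("obabel", c(f, "-orinchi"),
                                  stdout = TRUE, stderr = FALSE))
  out[startsWith(out, "RInChI=")][1]
}

# Engine-free reaction step from hand-written InChI bodies.
step_rec <- function(r, p, a = character(0), direction = "forward") {
  reaction_record(reactants = lapply(r, sc), products = lapply(p, sc),
                  agents = lapply(a, sc), direction = direction)
}

# Flow-consistent cascade chains: each step consumes some of the previous
# step's products plus fresh species, and makes fresh species.  (With sets
# standing in for stoichiometry, chains that consume one species in several
# steps have no well-defined sum, so the generator avoids them.)
mk_cascade <- function(n_steps = 3) {
  counter <- 0L
  fresh <- function(n) {
    counter <<- counter + n
    paste0("NM", (counter - n + 1):counter, "1/c1-2")
  }
  avail <- character(0)
  steps <- list()
  for (i in seq_len(n_steps)) {
    carry <- if (length(avail)) {
      avail[sample.int(length(avail)) <= sample(0:length(avail), 1)]
    } else character(0)
    r <- c(carry, fresh(sample(1:2, 1)))
    p <- fresh(sample(1:2, 1))
    steps[[i]] <- step_rec(r, p, if (sample(0:1, 1)) fresh(1) else character(0))
    avail <- p
  }
  steps
}

random_payload <- function() {
  n <- sample(0:40, 1)
  paste(sample(c(LETTERS, letters, 0:9, "/", "!", ",", "-", "(", ")"),
               n, replace = TRUE), collapse = "")
}
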