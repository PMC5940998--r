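# Deterministic toy-reaction generator.
#
# Fixture molecules are composed as V2000 molfiles from a parameterized
# library of small structures (linear alkanes, alcohols, diols, amines,
# thiols, carboxylic acids, their anions, and chiral secondary alcohols of
# varying chain length).  Every library entry has a distinct InChI; charged
# entries exercise the /p proton sublayer and chiral ones the /t /m /s minor
# sublayers.  The same seed always yields byte-identical files.

fixture_coords <- function(n) {
  # zigzag layout; non-collinear so wedge bonds define real stereocentres
  list(x = (seq_len(n) - 1) * 0.87, y = rep_len(c(0, 0.5), n))
}

compose_molfile <- function(elements, bonds = NULL, charges = NULL,
                            title = "") {
  n <- length(elements)
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  xy <- fixture_coords(n)
  lines <- c(title, "  rxnid", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xy$x[i], xy$y[i], 0, elements[i]))
  }
  if (nb) {
    for (j in seq_len(nb)) {
      stereo <- if (ncol(bonds) >= 4L) bonds[j, 4] else 0L
      lines <- c(lines, sprintf("%3d%3d%3d%3d  0  0  0",
                                bonds[j, 1], bonds[j, 2], bonds[j, 3], stereo))
    }
  }
  if (!is.null(charges)) {
    for (k in seq_len(nrow(charges))) {
      lines <- c(lines, sprintf("M  CHG%3d%4d%4d", 1L, charges[k, 1], charges[k, 2]))
    }
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

chain_bonds <- function(n) {
  if (n < 2L) return(NULL)
  cbind(seq_len(n - 1L), seq(2L, n), 1L, 0L)
}

# ---- the molecule library ---------------------------------------------------

fixture_families <- list(
  alkane = list(min_n = 1L, build = function(n) {
    compose_molfile(rep("C", n), chain_bonds(n), title = paste0("alkane-", n))
  }),
  alcohol = list(min_n = 1L, build = function(n) {
    compose_molfile(c(rep("C", n), "O"), chain_bonds(n + 1L),
                    title = paste0("alcohol-", n))
  }),
  diol = list(min_n = 2L, build = function(n) {
    ele <- c("O", rep("C", n), "O")
    compose_molfile(ele, chain_bonds(n + 2L), title = paste0("diol-", n))
  }),
  amine = list(min_n = 1L, build = function(n) {
    compose_molfile(c(rep("C", n), "N"), chain_bonds(n + 1L),
                    title = paste0("amine-", n))
  }),
  thiol = list(min_n = 1L, build = function(n) {
    compose_molfile(c(rep("C", n), "S"), chain_bonds(n + 1L),
                    title = paste0("thiol-", n))
  }),
  acid = list(min_n = 1L, build = function(n) {
    # C1 is the carboxyl carbon: =O at n+1, -OH at n+2
    bonds <- rbind(chain_bonds(n), c(1L, n + 1L, 2L, 0L), c(1L, n + 2L, 1L, 0L))
    compose_molfile(c(rep("C", n), "O", "O"), bonds,
                    title = paste0("acid-", n))
  }),
  carboxylate = list(min_n = 1L, build = function(n) {
    bonds <- rbind(chain_bonds(n), c(1L, n + 1L, 2L, 0L), c(1L, n + 2L, 1L, 0L))
    compose_molfile(c(rep("C", n), "O", "O"), bonds,
                    charges = cbind(n + 2L, -1L),
                    title = paste0("carboxylate-", n))
  }),
  chiral_alcohol = list(min_n = 4L, build = function(n) {
    # secondary alcohol on C2 with a wedge bond: a genuine stereocentre
    bonds <- rbind(chain_bonds(n), c(2L, n + 1L, 1L, 1L))
    compose_molfile(c(rep("C", n), "O"), bonds,
                    title = paste0("chiral-alcohol-", n))
  })
)

fixture_catalog <- function(max_n = 12L) {
  rows <- do.call(rbind, lapply(names(fixture_families), function(fam) {
    lo <- fixture_families[[fam]]$min_n
    if (lo > max_n) return(NULL)
    data.frame(family = fam, n = seq(lo, max_n), stringsAsFactors = FALSE)
  }))
  rows[order(rows$family, rows$n), , drop = FALSE]
}

fixture_molfile <- function(family, n) {
  fixture_families[[family]]$build(n)
}

no_structure_molfile <- function(label = "no-structure") {
  compose_molfile(character(0), title = label)
}

rxn_text <- function(reactant_mols, product_mols, agent_mols = list(),
                     name = "rxnid fixture") {
  out <- c("$RXN", name, "  rxnid", "",
           sprintf("%3d%3d", length(reactant_mols), length(product_mols)))
  for (m in c(reactant_mols, product_mols)) out <- c(out, "$MOL", m)
  if (length(agent_mols)) {
    out <- c(out, AGENT_SENTINEL)
    for (m in agent_mols) out <- c(out, "$MOL", m)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

rd_text <- function(reactant_mols, product_mols, agent_mols = list(),
                    name = "rxnid fixture") {
  out <- c("$RDFILE 1", "$DATM rxnid", "$RFMT")
  rxn <- rxn_text(reactant_mols, product_mols, name = name)
  out <- c(out, strsplit(sub("\n$", "", rxn), "\n", fixed = TRUE)[[1]])
  for (i in seq_along(agent_mols)) {
    out <- c(out, sprintf("$DTYPE CATALYST(%d)", i), "$DATUM $MFMT",
             agent_mols[[i]])
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Generate a deterministic toy reaction fixture
#'
#' Draws distinct molecules from the built-in structure library and composes
#' an RXN file, an equivalent single-record RD file (agents as catalyst data
#' fields), and the expected [reaction_record()].  The same seed always
#' produces byte-identical text.
#'
#' @param seed Integer seed; all randomness is local to the call.
#' @param n_react,n_prod,n_agents Component counts per group.
#' @param n_nostruct Integer triple: number of no-structure components to
#'   inject into reactants, products and agents respectively.
#' @param max_chain Largest chain length drawn from the library (bounds the
#'   generator space).
#' @return A list with elements `rxn` (RXN text), `rd` (RD text), `record`
#'   (the expected record, engine-identified), and `molfiles`.
#' @examples
#' \dontrun{
#' fx <- make_fixture(1, n_react = 2, n_prod = 2, n_agents = 1)
#' rinchi(fx$record)
#' }
#' @export
make_fixture <- function(seed, n_react = 2L, n_prod = 2L, n_agents = 0L,
                         n_nostruct = c(0L, 0L, 0L), max_chain = 12L) {
  stopifnot(n_react >= 0L, n_prod >= 0L, n_agents >= 0L,
            length(n_nostruct) == 3L, all(n_nostruct >= 0L))
  catalog <- fixture_catalog(max_chain)
  need <- n_react + n_prod + n_agents
  if (need > nrow(catalog)) {
    stop_rxnid("requested ", need, " distinct molecules but the generator ",
               "space holds only ", nrow(catalog), class = "rxnid_fixture_error")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  pick <- catalog[sample.int(nrow(catalog), need), , drop = FALSE]
  mols <- lapply(seq_len(need), function(i) fixture_molfile(pick$family[i], pick$n[i]))
  react <- mols[seq_len(n_react)]
  prod <- mols[n_react + seq_len(n_prod)]
  agent <- mols[n_react + n_prod + seq_len(n_agents)]

  ns <- lapply(seq_len(3L), function(g) {
    replicate(n_nostruct[g], no_structure_molfile(), simplify = FALSE)
  })
  react_all <- c(react, ns[[1]])
  prod_all <- c(prod, ns[[2]])
  agent_all <- c(agent, ns[[3]])

  list(
    rxn = rxn_text(react_all, prod_all, agent_all,
                   name = sprintf("rxnid fixture seed=%d", seed)),
    rd = rd_text(react_all, prod_all, agent_all,
                 name = sprintf("rxnid fixture seed=%d", seed)),
    record = reaction_record(reactants = react_all, products = prod_all,
                             agents = agent_all, direction = "forward"),
    molfiles = list(reactants = react_all, products = prod_all,
                    agents = agent_all),
    seed = seed
  )
}

# ---- the ethyl acetate hydrolysis example -----------------------------------

example_molfiles <- function() {
  list(
    `ethyl acetate` = compose_molfile(
      c("C", "C", "O", "C", "C", "O"),
      rbind(c(1L, 2L, 1L, 0L), c(2L, 3L, 1L, 0L), c(3L, 4L, 1L, 0L),
            c(4L, 5L, 1L, 0L), c(4L, 6L, 2L, 0L)),
      title = "ethyl acetate"),
    water = compose_molfile("O", title = "water"),
    `acetic acid` = compose_molfile(
      c("C", "C", "O", "O"),
      rbind(c(1L, 2L, 1L, 0L), c(2L, 3L, 2L, 0L), c(2L, 4L, 1L, 0L)),
      title = "acetic acid"),
    ethanol = compose_molfile(
      c("C", "C", "O"), rbind(c(1L, 2L, 1L, 0L), c(2L, 3L, 1L, 0L)),
      title = "ethanol"),
    `sulfuric acid` = compose_molfile(
      c("S", "O", "O", "O", "O"),
      rbind(c(1L, 2L, 2L, 0L), c(1L, 3L, 2L, 0L), c(1L, 4L, 1L, 0L),
            c(1L, 5L, 1L, 0L)),
      title = "sulfuric acid")
  )
}

#' A hand-drawn molfile from the hydrolysis example
#'
#' @param name One of `"ethyl acetate"`, `"water"`, `"acetic acid"`,
#'   `"ethanol"`, `"sulfuric acid"`.
#' @return The V2000 molfile block as a string.
#' @export
example_molfile <- function(name) {
  mols <- example_molfiles()
  if (!name %in% names(mols)) {
    stop_rxnid("unknown example molecule: ", name,
               " (expected one of: ", paste(names(mols), collapse = ", "), ")",
               class = "rxnid_fixture_error")
  }
  mols[[name]]
}

#' The ethyl acetate hydrolysis equilibrium
#'
#' The classic worked example: ethyl acetate + water, in equilibrium with
#' acetic acid + ethanol, with sulfuric acid as the agent (catalyst).  All
#' five molfiles are drawn in-package and identified through the engine.
#'
#' @return A [reaction_record()] with direction `"equilibrium"`.
#' @export
hydrolysis_example <- function() {
  mols <- example_molfiles()
  reaction_record(
    reactants = list(mols$`ethyl acetate`, mols$water),
    products = list(mols$`acetic acid`, mols$ethanol),
    agents = list(mols$`sulfuric acid`),
    direction = "equilibrium"
  )
}
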