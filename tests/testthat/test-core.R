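test_that("group serialization sorts byte-wise and joins with '!'", {
  acetic <- "C2H4O2/c1-2(3)4/h1H3,(H,3,4)"
  ethanol <- "C2H6O/c1-2-3/h3H,2H2,1H3"
  expect_equal(serialize_group(c(ethanol, acetic)),
               paste0(acetic, "!", ethanol))
  expect_equal(serialize_group(character(0)), "")

  # brute-force oracle: the serialized string is the minimum over all
  # permutation joins
  set.seed(7)
  for (rep in 1:10) {
    bodies <- unique(replicate(5, paste(sample(c(LETTERS, 0:9, "/"), 6,
                                               replace = TRUE), collapse = "")))
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
      }
      out
    }
    joins <- vapply(perms(bodies), paste, character(1), collapse = "!")
    expect_equal(serialize_group(bodies), sort(joins, method = "radix")[1])
  }
})

test_that("layer assignment puts the alphabetically smaller group first", {
  layers <- assign_layers(normalize_record(hydrolysis_example()))
  # opposite way around to the drawing: products (acetic acid + ethanol)
  # serialize first and become layer two
  expect_equal(layers$group_a$body,
               c("C2H4O2/c1-2(3)4/h1H3,(H,3,4)", "C2H6O/c1-2-3/h3H,2H2,1H3"))
  expect_equal(layers$group_b$body,
               c("C4H8O2/c1-3-6-4(2)5/h3H2,1-2H3", "H2O/h1H2"))
  expect_equal(layers$agents$body, "H2O4S/c1-5(2,3)4/h(H2,1,2,3,4)")
  expect_equal(layers$direction, "=")

  # same reaction driven forward: the flag records that layer three holds
  # the starting materials
  fwd <- hydrolysis_example()
  fwd$direction <- "forward"
  expect_equal(assign_layers(normalize_record(fwd))$direction, "-")
  bwd <- hydrolysis_example()
  bwd$direction <- "backward"
  expect_equal(assign_layers(normalize_record(bwd))$direction, "+")
})

test_that("an empty group sorts first and direction maps accordingly", {
  rec <- reaction_record(products = list(sc("X1/c1-2")), direction = "forward")
  layers <- assign_layers(normalize_record(rec))
  expect_equal(nrow(layers$group_a), 0L)
  expect_equal(layers$group_b$body, "X1/c1-2")
  expect_equal(layers$direction, "+")
})

test_that("the no-structure layer drops trailing zero sections", {
  expect_equal(build_no_structure_layer(c(2, 3, 4)), "/u2-3-4")
  expect_equal(build_no_structure_layer(c(2, 3, 0)), "/u2-3")
  expect_equal(build_no_structure_layer(c(0, 0, 0)), "")
  expect_equal(build_no_structure_layer(c(0, 0, 1)), "/u0-0-1")
  expect_error(build_no_structure_layer(c(-1, 0, 0)), class = "rxnid_layer_error")
})

test_that("the worked example serializes to the reference RInChI", {
  expect_equal(rinchi(hydrolysis_example()), REF$rinchi)
})

test_that("degenerate reactions serialize with separators omitted", {
  expect_equal(build_rinchi(reaction_record(direction = "unspecified")),
               "RInChI=1.00.1S")
  # one no-structure reactant only; trailing zero sections are omitted
  ns <- reaction_record(reactants = list(structure_component()),
                        direction = "forward")
  expect_equal(build_rinchi(ns), "RInChI=1.00.1S/d+/u1")
  # no agents: trailing "<>" omitted but groups kept
  rec <- reaction_record(reactants = list(sc("A1/c1-2")),
                         products = list(sc("B1/c1-2")))
  expect_equal(build_rinchi(rec), "RInChI=1.00.1S/A1/c1-2<>B1/c1-2/d+")
})

test_that("parsing inverts building", {
  layers <- parse_rinchi(REF$rinchi)
  expect_equal(nrow(layers$group_a), 2L)
  expect_equal(nrow(layers$group_b), 2L)
  expect_equal(nrow(layers$agents), 1L)
  expect_equal(layers$direction, "=")
  expect_equal(build_rinchi(layers), REF$rinchi)

  empty <- parse_rinchi("RInChI=1.00.1S")
  expect_equal(nrow(empty$group_a) + nrow(empty$group_b) + nrow(empty$agents), 0L)
  expect_true(is.na(empty$direction))

  # zero-padded sixth layers parse to the same counts and re-emit canonically
  u <- parse_rinchi("RInChI=1.00.1S/d+/u1-0-0")
  expect_equal(u$u, c(1L, 0L, 0L))
  expect_equal(build_rinchi(u), "RInChI=1.00.1S/d+/u1")
  expect_equal(parse_rinchi("RInChI=1.00.1S/d+/u1")$u, c(1L, 0L, 0L))
})

test_that("parse validation reports malformed strings", {
  expect_error(parse_rinchi("RInChI=2.00.1S/A"), class = "rxnid_parse_error")
  expect_error(parse_rinchi("RInChI=1.00.1S/B!A<>C"), class = "rxnid_parse_error")
  expect_error(parse_rinchi("RInChI=1.00.1S/A!A<>C"), class = "rxnid_parse_error")
  expect_error(parse_rinchi("RInChI=1.00.1S/A<>B/dx"), class = "rxnid_parse_error")
  expect_error(parse_rinchi("RInChI=1.00.1S/A<>B<>C<>D"), class = "rxnid_parse_error")
  # lenient mode re-sorts instead of failing
  lax <- parse_rinchi("RInChI=1.00.1S/B!A<>C", strict = FALSE)
  expect_equal(lax$group_a$body, c("A", "B"))
  # the typographic minus of printed text is accepted
  expect_equal(parse_rinchi("RInChI=1.00.1S/A<>B/d−")$direction, "-")
})

test_that("round trip holds over randomized fixture reactions", {
  for (seed in 1:15) {
    shape <- c(seed %% 3 + 1L, (seed %/% 3) %% 3, seed %% 2)
    fx <- make_fixture(seed, shape[1], shape[2], shape[3],
                       n_nostruct = c(seed %% 2, 0L, (seed %/% 2) %% 2))
    s <- rinchi(fx$record)
    expect_equal(build_rinchi(parse_rinchi(s)), s)
  }
})

test_that("the RAuxInfo mirrors the RInChI component order", {
  raux <- rauxinfo(hydrolysis_example())
  expect_match(raux, "^RAuxInfo=1\\.00\\.1/")
  segs <- strsplit(sub("^RAuxInfo=1\\.00\\.1/", "", raux), "<>", fixed = TRUE)[[1]]
  expect_length(segs, 3L)
  expect_length(strsplit(segs[1], "!", fixed = TRUE)[[1]], 2L)
  expect_length(strsplit(segs[2], "!", fixed = TRUE)[[1]], 2L)
  # five components in RInChI order: acetic acid, ethanol, EtOAc, water, H2SO4
  expect_match(segs[1], "rA:4CCOO")   # acetic acid first
  expect_match(segs[2], "rA:6CCOCCO") # ethyl acetate third
  expect_match(segs[3], "rA:5SOOOO")  # sulfuric acid last

  expect_equal(build_rauxinfo(reaction_record()), "RAuxInfo=1.00.1")
  # a structured component without engine AuxInfo cannot be serialized
  expect_error(build_rauxinfo(reaction_record(reactants = list(sc("A1/c1-2")))),
               class = "rxnid_aux_error")
})

test_that("input order never affects RInChI or RAuxInfo", {
  fx <- make_fixture(101, 3, 2, 2)
  rec <- fx$record
  for (i in 1:5) {
    shuf <- function(x) x[sample.int(length(x))]
    rec2 <- reaction_record(reactants = shuf(rec$reactants),
                            products = shuf(rec$products),
                            agents = shuf(rec$agents),
                            direction = rec$direction)
    expect_equal(rinchi(rec2), rinchi(rec))
    expect_equal(rauxinfo(rec2), rauxinfo(rec))
  }
})

test_that("swapping roles flips only the direction flag", {
  for (seed in c(5, 23, 77)) {
    fx <- make_fixture(seed, 2, 2, 1)
    fwd <- rinchi(fx$record)
    swapped <- reaction_record(reactants = fx$record$products,
                               products = fx$record$reactants,
                               agents = fx$record$agents,
                               direction = "forward")
    rev <- rinchi(swapped)
    expect_equal(sub("/d[+-]$", "", rev), sub("/d[+-]$", "", fwd))
    flag <- function(s) regmatches(s, regexpr("/d[+-]$", s))
    expect_true(flag(fwd) != flag(rev))
    expect_setequal(c(flag(fwd), flag(rev)), c("/d+", "/d-"))
  }
})

test_that("our serializer agrees with an independent RInChI writer", {
  for (seed in c(3, 14, 59)) {
    fx <- make_fixture(seed, 2, 2, 0)
    expect_equal(rinchi(fx$record), obabel_rinchi(fx$rxn))
  }
})
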