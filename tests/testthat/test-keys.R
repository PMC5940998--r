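test_that("empty payloads give the canonical blank hash strings", {
  expect_equal(hash_letters("", 10), "UHFFFADPSC")
  expect_equal(hash_letters("", 4), "UHFF")
  expect_error(hash_letters("", 7), class = "rxnid_key_error")
})

test_that("the letter hash matches an independent reference implementation", {
  set.seed(11)
  payloads <- c("", replicate(40, random_payload()))
  for (p in payloads) {
    for (n in c(4L, 10L, 12L, 17L)) {
      expect_equal(hash_letters(p, n), oracle_hash_letters(p, n))
    }
  }
})

test_that("letter hashes are deterministic and collision-shy", {
  set.seed(12)
  payloads <- unique(replicate(3000, random_payload()))
  h <- vapply(payloads, hash_letters, character(1), n = 10L)
  expect_equal(anyDuplicated(h), 0L)
  expect_true(all(grepl("^[A-Z]{10}$", h)))
  expect_equal(hash_letters(payloads[1], 10), h[[1]])
})

test_that("the single-letter encodings follow the published mapping", {
  expect_equal(direction_letter("="), "E")
  expect_equal(direction_letter("+"), "F")
  expect_equal(direction_letter("-"), "B")
  expect_equal(direction_letter(NA), "U")

  expect_equal(protonation_letter(0), "N")
  expect_equal(protonation_letter(-1), "M")
  expect_equal(protonation_letter(-2), "L")
  expect_equal(protonation_letter(1), "O")
  expect_equal(protonation_letter(2), "P")
  expect_warning(expect_equal(protonation_letter(-20), "A"))
  expect_warning(expect_equal(protonation_letter(20), "Z"))

  expect_equal(nostructure_letter(0), "Z")
  expect_equal(nostructure_letter(1), "A")
  expect_equal(nostructure_letter(2), "B")
  expect_equal(nostructure_letter(25), "Y")
  expect_warning(expect_equal(nostructure_letter(40), "Y"))
})

test_that("the Long key lists every component InChIKey in layer order", {
  lk <- long_key(hydrolysis_example())
  expect_match(lk, "^Long-RInChIKey=SA-EUHFF-", fixed = FALSE)
  # window-parser oracle: pull the 27-character InChIKeys back out in order
  keys <- regmatches(lk, gregexpr("[A-Z]{14}-[A-Z]{10}-[A-Z]", lk))[[1]]
  expect_equal(keys, unname(REF$inchikey[c("acetic acid", "ethanol",
                                           "ethyl acetate", "water",
                                           "sulfuric acid")]))
  # layers two/three and three/four separated by double hyphens
  expect_match(lk, paste0(REF$inchikey[["ethanol"]], "--",
                          REF$inchikey[["ethyl acetate"]]), fixed = TRUE)
  expect_match(lk, paste0(REF$inchikey[["water"]], "--",
                          REF$inchikey[["sulfuric acid"]]), fixed = TRUE)
})

test_that("the Short key has the published layout for the worked example", {
  sk <- short_key(hydrolysis_example())
  body <- sub("^Short-RInChIKey=", "", sk)
  parts <- strsplit(body, "-", fixed = TRUE)[[1]]
  expect_length(parts, 9L)
  expect_equal(parts[1], "SA")
  expect_equal(parts[2], "EUHFF")
  expect_equal(parts[3], REF$short_l2_hash)  # acetic acid + ethanol majors
  expect_match(parts[4], "^[A-Z]{10}$")
  expect_match(parts[5], "^[A-Z]{10}$")
  # no stereochemistry, zero protonation: the three minor groups are blank
  expect_equal(parts[6:8], rep("NUHFF", 3))
  expect_equal(parts[9], "ZZZ")
  expect_equal(nchar(body), 63L)
  expect_equal(nchar(gsub("-", "", body)), 55L)
})

test_that("an all-empty reaction hashes to the blank Short key", {
  sk <- short_key(reaction_record(direction = "unspecified"))
  expect_equal(sk, paste0("Short-RInChIKey=SA-UUHFF-",
                          "UHFFFADPSC-UHFFFADPSC-UHFFFADPSC-",
                          "NUHFF-NUHFF-NUHFF-ZZZ"))
})

test_that("the Web key for the worked example matches the published value", {
  expect_equal(web_key(hydrolysis_example()), REF$web_key)
})

test_that("the Web key ignores role assignment", {
  base <- hydrolysis_example()
  # water demoted from reactant to agent
  moved <- reaction_record(reactants = list(base$reactants[[1]]),
                           products = base$products,
                           agents = c(base$agents, list(base$reactants[[2]])),
                           direction = "equilibrium")
  expect_equal(web_key(moved), REF$web_key)
  expect_false(identical(short_key(moved), short_key(base)))

  # a body duplicated across layers is removed before hashing
  dup <- reaction_record(reactants = base$reactants,
                         products = base$products,
                         agents = c(base$agents, list(base$reactants[[2]])),
                         direction = "equilibrium")
  expect_equal(web_key(dup), REF$web_key)
})

test_that("protonation letters appear in the layer carrying the charge", {
  acid <- rxnid:::fixture_molfile("acid", 2)
  acetate <- rxnid:::fixture_molfile("carboxylate", 2)
  ethanol <- example_molfile("ethanol")
  rec <- reaction_record(reactants = list(acid), products = list(acetate, ethanol))
  layers <- assign_layers(normalize_record(rec))
  sk <- short_key(layers)
  parts <- strsplit(sub("^Short-RInChIKey=", "", sk), "-", fixed = TRUE)[[1]]
  # whichever layer holds the acetate anion opens its minor group with "M"
  anion_body <- inchi_body(molfile_to_identity(acetate)$inchi)
  anion_layer <- if (anion_body %in% layers$group_a$body) 6L else 7L
  expect_equal(substr(parts[anion_layer], 1, 1), "M")
  other <- setdiff(6:7, anion_layer)
  expect_equal(substr(parts[other], 1, 1), "N")

  wk <- web_key(layers)
  expect_equal(substr(sub("^.*-", "", wk), 1, 1), "M")  # total balance -1
})

test_that("key shapes hold across randomized fixtures", {
  for (seed in 1:40) {
    fx <- make_fixture(seed, seed %% 4, (seed %/% 2) %% 3, seed %% 3,
                       n_nostruct = c(seed %% 2, (seed %/% 3) %% 2, 0L),
                       max_chain = 8L)
    keys <- rinchi_keys(fx$record)
    body <- sub("^Short-RInChIKey=", "", keys$short)
    expect_equal(nchar(body), 63L)
    expect_equal(nchar(gsub("-", "", body)), 55L)
    expect_equal(lengths(regmatches(body, gregexpr("-", body))), 8L)
    expect_equal(nchar(keys$web), 47L)
    # long and short keys share the "SA-<dir>UHFF" header
    expect_equal(substr(sub("^Long-RInChIKey=", "", keys$long), 1, 8),
                 substr(body, 1, 8))
  }
})

test_that("bare keys drop their labels", {
  keys <- rinchi_keys(hydrolysis_example(), bare = TRUE)
  expect_false(any(grepl("=", unlist(keys), fixed = TRUE)))
  expect_equal(nchar(keys$web), 33L)
})

test_that("keys can be computed from a parsed RInChI string", {
  keys <- rinchi_keys(REF$rinchi)
  expect_equal(keys$web, REF$web_key)
  expect_equal(keys$short, short_key(hydrolysis_example()))
  # InChIKeys re-derived through the engine for the long key
  expect_match(keys$long, REF$inchikey[["water"]], fixed = TRUE)
})
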