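Package: rxnid
Title: Reaction InChI (RInChI) Identifiers, Keys and Reaction File Conversion
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds the six-layer Reaction InChI (RInChI) string, the layered
    RAuxInfo auxiliary string, and the three hashed reaction keys
    (Long-, Short- and Web-RInChIKey) from MDL RXN and RD reaction files or
    from per-component molfiles.  Structure identifiers are delegated to the
    standard InChI engine bundled with Open Babel; the package contributes the
    reaction-level layering, normalization, serialization, parsing, SHA-256
    based key hashing with the InChIKey base-26 letter encoding, multistep
    reaction addition, and key-based comparison for database deduplication.
    A deterministic fixture generator composes toy V2000 molfiles so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Open Babel (obabel on the PATH) for InChI generation
Imports:
    openssl,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
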