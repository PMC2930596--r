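test_that("Hill formulas parse to element maps and format back", {
  expect_equal(parse_formula("C3H4O3"), c(C = 3L, H = 4L, O = 3L))
  expect_equal(parse_formula("C6H13O9P"), c(C = 6L, H = 13L, O = 9L, P = 1L))
  expect_equal(format_formula(c(C = 3L, H = 4L, O = 3L)), "C3H4O3")
  expect_equal(format_formula(c(P = 1L, O = 4L, H = 3L)), "H3O4P")
  expect_equal(format_formula(parse_formula("C10H16N5O13P3")), "C10H16N5O13P3")
  expect_error(parse_formula("C3Xx4"), "unknown element")
  expect_null(parse_formula(""))
})

test_that("stoichiometry strings parse with mandatory explicit coefficients", {
  s <- parse_stoichiometry("1 Ath_C0001 + 1 Ath_C0002 = 1 Ath_C0003")
  expect_equal(s$substrates$id, c("Ath_C0001", "Ath_C0002"))
  expect_equal(s$substrates$coef, c(1, 1))
  expect_equal(s$products, data.frame(id = "Ath_C0003", coef = 1))
  s2 <- parse_stoichiometry("2 Ath_C0010 = 1 Ath_C0011")
  expect_equal(s2$substrates$coef, 2)
  expect_error(parse_stoichiometry("Ath_C0001 = 1 Ath_C0002"), "explicit")
  expect_error(parse_stoichiometry("1 A = 1 B = 1 C"), "exactly one")
  expect_error(parse_stoichiometry("1 A + 1 B"), "exactly one")
})

test_that("stoichiometry format/parse round-trips random reactions", {
  withr::with_seed(7, {
    for (k in 1:25) {
      ns <- sample(1:4, 1); np <- sample(1:4, 1)
      subs <- data.frame(id = sprintf("C%03d", sample(1:50, ns)),
                         coef = sample(c(1, 2, 3, 0.5), ns, replace = TRUE))
      prods <- data.frame(id = sprintf("C%03d", sample(51:99, np)),
                          coef = sample(c(1, 2, 1.5), np, replace = TRUE))
      s <- parse_stoichiometry(format_stoichiometry(subs, prods))
      expect_equal(s$substrates, subs)
      expect_equal(s$products, prods)
    }
  })
})

test_that("record constructors enforce their invariants", {
  expect_error(compound_record("A", "", "x"), "non-empty")
  expect_error(compound_record("A", "C1", character()), "names")
  expect_error(compound_record("A", "C1", "an alcohol", smiles = "CCO",
                               is_generic = TRUE), "generic")
  expect_error(reaction_record("A", "R1", side_df(C1 = 0), side_df(C2 = 1)),
               "positive")
  expect_error(reaction_record("A", "R1",
                               data.frame(id = character(), coef = numeric()),
                               side_df(C2 = 1)), "non-empty")
})

test_that("source databases reject duplicates and dangling references", {
  c1 <- compound_record("A", "C1", "alpha")
  c2 <- compound_record("A", "C2", "beta")
  r_ok <- reaction_record("A", "R1", side_df(C1 = 1), side_df(C2 = 1))
  expect_s3_class(source_db(list(c1, c2), list(r_ok), "A"), "gm_source_db")
  expect_error(source_db(list(c1, c1), list(), "A"), "duplicate")
  r_bad <- reaction_record("A", "R2", side_df(C1 = 1), side_df(CX999 = 1))
  expect_error(source_db(list(c1, c2), list(r_bad), "A"), "CX999")
})

test_that("the source dialect reads and writes loss-free", {
  dir <- withr::local_tempdir()
  cps <- list(
    compound_record("A", "C00022",
                    c("pyruvate", "pyruvic acid", "2-oxopropanoate"),
                    parse_formula("C3H4O3"), "CC(=O)C(=O)O", "KEGG:C00022"),
    compound_record("A", "C00069", "an alcohol", is_generic = TRUE)
  )
  rxs <- list(reaction_record("A", "R1", side_df(C00022 = 1),
                              side_df(C00069 = 2), c("1.1.1.1", "2.7.1.-"),
                              reversible = FALSE, pathways = c("p1", "p2")))
  db <- source_db(cps, rxs, "A")
  write_source_db(db, dir)
  db2 <- read_source_db(dir, "A")
  expect_equal(db2$compounds$C00022$names, cps[[1]]$names)
  expect_equal(db2$compounds$C00022$formula, cps[[1]]$formula)
  expect_equal(db2$compounds$C00022$xrefs, "KEGG:C00022")
  expect_true(db2$compounds$C00069$is_generic)
  expect_true(is.na(db2$compounds$C00069$smiles))
  expect_equal(db2$reactions$R1$ec, c("1.1.1.1", "2.7.1.-"))
  expect_false(db2$reactions$R1$reversible)
  expect_equal(db2$reactions$R1$products$coef, 2)
  # empty reactions table round-trips without error
  db0 <- source_db(cps, list(), "A")
  write_source_db(db0, file.path(dir, "empty"))
  expect_length(read_source_db(file.path(dir, "empty"), "A")$reactions, 0)
})

test_that("the parser names the offending line for malformed stoichiometry", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tnames\tformula\tsmiles\txrefs\tis_generic",
               "C1\tx\t\t\t\t0"), file.path(dir, "compounds.tsv"))
  writeLines(c("id\tstoichiometry\tec\treversible\tpathways",
               "R1\tC1 = 1 C1\t\t1\t"), file.path(dir, "reactions.tsv"))
  expect_error(read_source_db(dir, "A"), "line 2")
})

test_that("reconstruction TSVs are deterministic and round-trip byte-identically", {
  tca <- get_tca()
  dir <- withr::local_tempdir()
  write_reconstruction(tca$tiers$core, file.path(dir, "w1"))
  r2 <- read_reconstruction(file.path(dir, "w1"), "core")
  write_reconstruction(r2, file.path(dir, "w2"))
  for (f in c("compounds.tsv", "reactions.tsv")) {
    expect_identical(readLines(file.path(dir, "w1", f)),
                     readLines(file.path(dir, "w2", f)))
  }
  # stoichiometry column uses the "=" separator and explicit unit coefficients
  rx_lines <- readLines(file.path(dir, "w1", "reactions.tsv"))[-1]
  stoich_col <- vapply(strsplit(rx_lines, "\t"), `[[`, "", 4)
  expect_true(all(grepl(" = ", stoich_col)))
  expect_true(all(grepl("^[0-9]", stoich_col)))
})

test_that("a single-compound reconstruction writes one data row and an empty reaction table", {
  cp <- data.frame(local_id = "Ath_C0001", id_A = "C1", name_A = "x",
                   id_B = "B1", name_B = "x", evidence = "seed_xref",
                   name_probability = NA_real_, structure_tier = NA_character_,
                   stringsAsFactors = FALSE)
  recon <- reconstruction("core", cp, .empty_rx_df())
  dir <- withr::local_tempdir()
  write_reconstruction(recon, dir)
  expect_length(readLines(file.path(dir, "compounds.tsv")), 2)
  expect_length(readLines(file.path(dir, "reactions.tsv")), 1)
})

test_that("tier nesting and core completeness are enforced", {
  cp <- data.frame(local_id = "Ath_C0001", id_A = "C1", name_A = "x",
                   id_B = NA_character_, name_B = NA_character_,
                   evidence = NA_character_, name_probability = NA_real_,
                   structure_tier = NA_character_, stringsAsFactors = FALSE)
  expect_error(reconstruction("core", cp, .empty_rx_df()), "both databases")
  rx <- .empty_rx_df()
  row <- data.frame(local_id = "Ath_R0001", id_A = "R1", id_B = NA_character_,
                    ec = "", stringsAsFactors = FALSE)
  row$substrates <- list(data.frame(id = "Ath_C9999", coef = 1))
  row$products <- list(data.frame(id = "Ath_C0001", coef = 1))
  rx <- rbind(rx, row)
  expect_error(reconstruction("complete", cp, rx), "unknown compound")
})
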