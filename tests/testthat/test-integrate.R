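# Small hand-built databases exercising the matching engine's edge cases.

two_cp <- function(db, id, names, formula, smiles = NA_character_,
                   xrefs = character()) {
  compound_record(db, id, names, parse_formula(formula), smiles, xrefs)
}

test_that("seed matching uses cross-references and exact synonyms, injectively", {
  a1 <- two_cp("A", "C00022", c("pyruvate", "pyroracemic acid"), "C3H4O3")
  a2 <- two_cp("A", "C00031", "glucose", "C6H12O6")
  a3 <- two_cp("A", "C00001", "water", "H2O")
  b1 <- two_cp("B", "CPD-1", "a keto acid", "C3H4O3", xrefs = "KEGG:C00022")
  b2 <- two_cp("B", "CPD-2", c("dextrose", "glucose"), "C6H12O6")
  b3 <- two_cp("B", "CPD-3", "agua", "H2O")
  dbA <- source_db(list(a1, a2, a3), list(), "A")
  dbB <- source_db(list(b1, b2, b3), list(), "B")
  st <- seed_matches(dbA, dbB)
  expect_equal(nrow(st$cmatch), 2)
  expect_identical(st$cmatch$evidence[st$cmatch$id_A == "C00022"], "seed_xref")
  expect_identical(st$cmatch$id_B[st$cmatch$id_A == "C00031"], "CPD-2")
  expect_identical(st$cmatch$evidence[st$cmatch$id_A == "C00031"],
                   "exact_synonym")
  expect_false("C00001" %in% st$cmatch$id_A)
  # shared synonym in both records seeds a match ("pyroracemic acid")
  b1b <- two_cp("B", "CPD-1", c("pyroracemic acid"), "C3H4O3")
  st2 <- seed_matches(dbA, source_db(list(b1b, b2, b3), list(), "B"))
  expect_identical(st2$cmatch$evidence[st2$cmatch$id_A == "C00022"],
                   "exact_synonym")
  # disjoint databases match nothing
  st3 <- seed_matches(dbA, source_db(list(b3), list(), "B"))
  expect_equal(nrow(st3$cmatch), 0)
})

test_that("a compound claiming two partners is quarantined, not matched", {
  a1 <- two_cp("A", "C1", "alpha", "C3H4O3")
  b1 <- two_cp("B", "P1", "first", "C3H4O3", xrefs = "KEGG:C1")
  b2 <- two_cp("B", "P2", "second", "C3H4O3", xrefs = "KEGG:C1")
  st <- seed_matches(source_db(list(a1), list(), "A"),
                     source_db(list(b1, b2), list(), "B"))
  expect_equal(nrow(st$cmatch), 0)
  expect_equal(nrow(st$review), 2)
  expect_match(st$review$note[1], "one-to-many")
})

test_that("reaction comparison ignores protons and reversibility orientation", {
  # sucrose-6-phosphate hydrolysis, identical in both sources
  mk_db <- function() {
    cpsA <- list(two_cp("A", "S6P", "sucrose 6-phosphate", "C12H23O14P"),
                 two_cp("A", "H2O", "water", "H2O"),
                 two_cp("A", "SUC", "sucrose", "C12H22O11"),
                 two_cp("A", "PI", "phosphate", "H3PO4"),
                 two_cp("A", "HP", c("H+", "proton"), "H"))
    cpsB <- list(two_cp("B", "bS6P", "sucrose 6-phosphate", "C12H23O14P"),
                 two_cp("B", "bH2O", "water", "H2O"),
                 two_cp("B", "bSUC", "sucrose", "C12H22O11"),
                 two_cp("B", "bPI", "phosphate", "H3PO4"))
    list(A = cpsA, B = cpsB)
  }
  cps <- mk_db()
  rA <- reaction_record("A", "RA", side_df(S6P = 1, H2O = 1),
                        side_df(SUC = 1, PI = 1, HP = 2), "3.1.3.24")
  rB_fwd <- reaction_record("B", "RB", side_df(bS6P = 1, bH2O = 1),
                            side_df(bSUC = 1, bPI = 1), "3.1.3.24")
  rB_rev <- reaction_record("B", "RBr", side_df(bSUC = 1, bPI = 1),
                            side_df(bS6P = 1, bH2O = 1), "3.1.3.24")
  dbA <- source_db(cps$A, list(rA), "A")
  dbB <- source_db(cps$B, list(rB_fwd, rB_rev), "B")
  st <- seed_matches(dbA, dbB)
  expect_identical(compare_reactions(rA, rB_fwd, st)$status, "full_match")
  # flipped orientation still matches (directionality is ambiguous)
  expect_identical(compare_reactions(rA, rB_rev, st)$status, "full_match")
  # disjoint EC sets block a full match
  rB_ec <- reaction_record("B", "RBe", side_df(bS6P = 1, bH2O = 1),
                           side_df(bSUC = 1, bPI = 1), "1.1.1.1")
  expect_identical(compare_reactions(rA, rB_ec, st)$status, "incompatible")
  # coefficient mismatch on a mapped compound is incompatible
  rB_coef <- reaction_record("B", "RBc", side_df(bS6P = 2, bH2O = 1),
                             side_df(bSUC = 1, bPI = 1), "3.1.3.24")
  expect_identical(compare_reactions(rA, rB_coef, st)$status, "incompatible")
})

test_that("a single unknown participant pair is nominated as a candidate", {
  # acetyl-CoA activation agreeing on everything but the acetyl-adenylate
  cpsA <- list(two_cp("A", "ACA", "acetyl adenylate", "C12H16N5O8P",
                      "CC(=O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc23)C(O)C1O"),
               two_cp("A", "COA", "CoA", "C21H36N7O16P3S"),
               two_cp("A", "ACCOA", "acetyl-CoA", "C23H38N7O17P3S"),
               two_cp("A", "AMP", "AMP", "C10H14N5O7P"))
  cpsB <- list(two_cp("B", "bACA", "acetyl-adenylate", "C12H16N5O8P",
                      "CC(=O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc23)C(O)C1O"),
               two_cp("B", "bCOA", "CoA", "C21H36N7O16P3S"),
               two_cp("B", "bACCOA", "acetyl-CoA", "C23H38N7O17P3S"),
               two_cp("B", "bAMP", "AMP", "C10H14N5O7P"))
  rA <- reaction_record("A", "RA", side_df(ACA = 1, COA = 1),
                        side_df(ACCOA = 1, AMP = 1), "6.2.1.1")
  rB <- reaction_record("B", "RB", side_df(bACA = 1, bCOA = 1),
                        side_df(bACCOA = 1, bAMP = 1), "6.2.1.1")
  dbA <- source_db(cpsA, list(rA), "A")
  dbB <- source_db(cpsB, list(rB), "B")
  st <- seed_matches(dbA, dbB)
  res <- compare_reactions(rA, rB, st)
  expect_identical(res$status, "one_unknown")
  expect_identical(res$candidate$id_A, "ACA")
  expect_identical(res$candidate$id_B, "bACA")
  # full integration then accepts the pair and matches the reaction
  state <- integrate_databases(dbA, dbB, name_model = get_gen42()$state$name_model)
  expect_true(any(state$cmatch$id_A == "ACA" & state$cmatch$id_B == "bACA"))
  expect_equal(nrow(state$rmatch), 1)
})

test_that("acceptance requires enzyme, name and structure evidence jointly", {
  model <- get_gen42()$state$name_model
  cand <- function(ecA, ecB) list(id_A = "C00022", id_B = "CPD-X",
                                  ec_A = ecA, ec_B = ecB)
  dbA <- source_db(list(two_cp("A", "C00022", c("pyruvate"), "C3H4O3",
                               "CC(=O)C(=O)O")), list(), "A")
  mk_B <- function(names, formula, smiles = NA_character_) {
    source_db(list(two_cp("B", "CPD-X", names, formula, smiles)), list(), "B")
  }
  # all three criteria pass
  v <- accept_candidate(cand("2.7.1.40", "2.7.1.40"), dbA,
                        mk_B("pyruvic acid", "C3H3O3", "CC(=O)C(=O)O"), model)
  expect_identical(v$decision, "accept")
  expect_identical(v$structure_tier, "exact")
  # EC and formula pass but the name is unrelated -> review
  v2 <- accept_candidate(cand("2.7.1.40", "2.7.1.40"), dbA,
                         mk_B("completely unrelated", "C3H4O3"), model)
  expect_identical(v2$decision, "review")
  expect_false(v2$name_ok)
  expect_identical(v2$structure_tier, "formula_only")
  # partial EC precision is not enough to accept
  v3 <- accept_candidate(cand("2.7.1.-", "2.7.1.-"), dbA,
                         mk_B("pyruvic acid", "C3H4O3", "CC(=O)C(=O)O"), model)
  expect_identical(v3$decision, "review")
  expect_false(v3$ec_ok)
  # nothing passes -> reject
  v4 <- accept_candidate(cand("1.1.1.1", "2.7.1.40"), dbA,
                         mk_B("completely unrelated", "C6H12O6"), model)
  expect_identical(v4$decision, "reject")
})

test_that("iteration reaches a fixpoint and is monotone", {
  gen <- get_gen42()
  lg <- gen$state$log
  expect_equal(lg$new_compounds[nrow(lg)], 0)
  expect_equal(lg$new_reactions[nrow(lg)], 0)
  expect_true(all(diff(cumsum(lg$new_compounds)) >= 0))
  # injectivity of the final matching
  expect_false(anyDuplicated(gen$state$cmatch$id_A) > 0)
  expect_false(anyDuplicated(gen$state$cmatch$id_B) > 0)
  # disjoint databases reach the fixpoint immediately with nothing matched
  dbA <- source_db(list(two_cp("A", "X", "xenon compound", "C5H8O2")), list(), "A")
  dbB <- source_db(list(two_cp("B", "Y", "yttrium compound", "C7H8O3")), list(), "B")
  st <- integrate_databases(dbA, dbB, name_model = gen$state$name_model)
  expect_equal(nrow(st$cmatch), 0)
  expect_equal(nrow(st$rmatch), 0)
})

test_that("review decisions can be injected and conflicts are refused", {
  fx <- tca_fixture()
  model <- get_tca()$state$name_model
  # the ubiquinol generic/specific pair sits in the review queue
  st0 <- get_tca()$state
  expect_true(any(st0$review$id_A == "C00390" &
                    st0$review$id_B == "UBIQUINOL-8"))
  dec <- data.frame(id_A = "C00390", id_B = "UBIQUINOL-8",
                    decision = "accept", stringsAsFactors = FALSE)
  st1 <- integrate_databases(fx$dbA, fx$dbB, name_model = model,
                             review_decisions = dec)
  expect_true(any(st1$cmatch$id_A == "C00390" & st1$cmatch$evidence == "manual"))
  # with the quinol pair resolved, succinate dehydrogenase becomes core
  t1 <- assign_tiers(fx$dbA, fx$dbB, st1)
  expect_identical(unname(t1$reaction_tier["A:TCA01"]), "core")
  bad <- data.frame(id_A = "C00042", id_B = "UBIQUINOL-8",
                    decision = "accept", stringsAsFactors = FALSE)
  expect_error(integrate_databases(fx$dbA, fx$dbB, name_model = model,
                                   review_decisions = bad), "injective")
})

test_that("the review queue round-trips through its TSV form", {
  st <- get_tca()$state
  path <- withr::local_tempfile(fileext = ".tsv")
  write_review_queue(st, path)
  q <- read_review_queue(path)
  expect_equal(nrow(q), nrow(st$review))
  expect_true("decision" %in% names(q))
  expect_setequal(q$id_A, st$review$id_A)
})

test_that("tier assignment is nested and the anchoring rule re-checks", {
  for (get in list(get_disc, get_tca, get_gen42)) {
    r <- get()
    tiers <- r$tiers
    expect_true(all(tiers$core$compounds$local_id %in%
                      tiers$intermediate$compounds$local_id))
    expect_true(all(tiers$intermediate$compounds$local_id %in%
                      tiers$complete$compounds$local_id))
    expect_true(all(tiers$core$reactions$local_id %in%
                      tiers$intermediate$reactions$local_id))
    expect_true(all(tiers$intermediate$reactions$local_id %in%
                      tiers$complete$reactions$local_id))
    # every intermediate addition passes the full-side anchoring test
    core_cp <- tiers$core$compounds$local_id
    inter <- tiers$intermediate$reactions
    added <- setdiff(inter$local_id, tiers$core$reactions$local_id)
    for (lid in added) {
      i <- match(lid, inter$local_id)
      s_in <- all(inter$substrates[[i]]$id %in% core_cp)
      p_in <- all(inter$products[[i]]$id %in% core_cp)
      expect_true(s_in || p_in, info = lid)
    }
    # every source reaction appears in exactly one innermost tier
    expect_setequal(names(r$tiers$reaction_tier),
                    c(paste0("A:", names(r$fx$dbA$reactions)),
                      paste0("B:", names(r$fx$dbB$reactions))))
    # local identifier scheme
    expect_true(all(grepl("^Ath_C[0-9]{4}$", tiers$complete$compounds$local_id)))
    expect_true(all(grepl("^Ath_R[0-9]{4}$", tiers$complete$reactions$local_id)))
    # protons never appear in reconstruction reactions
    prot <- c(gemmerge:::.proton_ids(r$fx$dbA),
              gemmerge:::.proton_ids(r$fx$dbB))
    if (length(prot)) {
      all_ids <- unlist(lapply(seq_len(nrow(tiers$complete$reactions)), function(i) {
        c(tiers$complete$reactions$substrates[[i]]$id,
          tiers$complete$reactions$products[[i]]$id)
      }))
      banned <- tiers$complete$compounds$local_id[
        !is.na(tiers$complete$compounds$id_A) &
          tiers$complete$compounds$id_A %in% prot]
      expect_length(intersect(all_ids, banned), 0)
    }
  }
})

test_that("tier assignment is independent of input record order", {
  fx <- discrepancy_fixture()
  model <- get_disc()$state$name_model
  base <- get_disc()$tiers$reaction_tier
  withr::with_seed(8, {
    dbA2 <- source_db(sample(fx$dbA$compounds), sample(fx$dbA$reactions), "A")
    dbB2 <- source_db(sample(fx$dbB$compounds), sample(fx$dbB$reactions), "B")
  })
  st2 <- integrate_databases(dbA2, dbB2, name_model = model)
  t2 <- assign_tiers(dbA2, dbB2, st2)
  expect_identical(t2$reaction_tier[names(base)], base)
})

test_that("pathway coverage tabulates EC attribution per tier", {
  tiers <- get_tca()$tiers
  pm <- data.frame(
    pathway = c(rep("cycle", 4), rep("absent", 2)),
    ec = c("4.2.1.2", "1.1.1.37", "1.2.4.2", "9.9.9.9", "7.7.7.7", "8.8.8.8"),
    stringsAsFactors = FALSE
  )
  cov <- pathway_coverage(tiers, pm)
  expect_equal(nrow(cov), 1)   # pathway with no EC in either source is dropped
  row <- cov[cov$pathway == "cycle", ]
  expect_equal(row$n_total, 3)        # 9.9.9.9 is in neither source
  expect_equal(row$n_core, 2)         # fumarase + malate dehydrogenase
  expect_equal(row$pct_core, 100 * 2 / 3)
  expect_equal(row$n_intermediate, 3) # ketoglutarate dehydrogenase joins
  expect_equal(row$n_complete, 3)
  expect_equal(nrow(pathway_coverage(tiers, pm[0, ])), 0)
  # core coverage cannot exceed intermediate coverage on the cycle fixture
  expect_lte(row$pct_core, row$pct_intermediate)
})
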