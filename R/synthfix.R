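# Deterministic generator of paired synthetic databases with ground truth.
#
# A bundled template library (~50 real small molecules with valid SMILES or
# curated formulas, and ~40 elementally balanced reactions from central
# carbon/nitrogen metabolism) provides chemically valid raw material.  The
# generator emits two database views of a sampled reaction network and
# plants the discrepancy classes observed between real metabolic databases:
#   - synonym variants ("-ic acid" vs "-ate" forms) with no exact overlap,
#     so identity is only recoverable through reaction context plus the
#     name classifier;
#   - proton-count differences (explicit H+ participants, formula H +/- 1);
#   - alternative cofactors (an ATP/ADP reaction duplicated with GTP/GDP in
#     one source only);
#   - generic compound classes ("an alcohol") used by one source;
#   - structural errors (a deleted functional group in one source);
#   - one-source-only reactions, either anchored to well-identified
#     compounds or floating free.
# Every reaction with formulas on both sides balances on non-hydrogen
# elements, so the mass vector of summed non-hydrogen atomic counts is a
# positive conserved witness: the planted core subnetwork is
# stoichiometrically consistent by construction.

.tpl_cache <- new.env(parent = emptyenv())

#' Bundled template library of compounds and balanced reactions
#'
#' @return list with data.frames `compounds` (id, name, synonyms, smiles,
#'   formula, chebi, is_generic) and `reactions` (id, equation, ec, pathway).
#' @export
template_library <- function() {
  if (is.null(.tpl_cache$tpl)) {
    dir <- system.file("extdata", package = "gemmerge")
    if (!nzchar(dir) || !file.exists(file.path(dir, "template_compounds.tsv"))) {
      dir <- "inst/extdata"   # in-source use (tests before installation)
    }
    cp <- utils::read.delim(file.path(dir, "template_compounds.tsv"),
                            colClasses = "character", na.strings = NULL,
                            check.names = FALSE)
    rx <- utils::read.delim(file.path(dir, "template_reactions.tsv"),
                            colClasses = "character", na.strings = NULL,
                            check.names = FALSE)
    .tpl_cache$tpl <- list(compounds = cp, reactions = rx)
  }
  .tpl_cache$tpl
}

.tpl_row <- function(id) {
  cp <- template_library()$compounds
  i <- match(id, cp$id)
  if (is.na(i)) stop_gm("unknown template compound: ", id)
  list(id = id, name = cp$name[i],
       synonyms = c(cp$name[i], .split_field(cp$synonyms[i], "|")),
       smiles = if (nzchar(cp$smiles[i])) cp$smiles[i] else NA_character_,
       formula = if (nzchar(cp$formula[i])) parse_formula(cp$formula[i]) else NULL,
       chebi = cp$chebi[i], is_generic = cp$is_generic[i] == "1")
}

#' Fixture generation parameters
#'
#' Defaults emulate a pair of curated metabolic databases of modest but
#' realistic discordance: about a third of shared compounds are only
#' recoverable through the name classifier, cross-references exist for
#' roughly 40 percent, a fifth of shared reactions disagree on protons, and
#' each source carries a handful of private reactions.
#'
#' @param n_shared_reactions reactions present (in some form) in both
#'   databases.
#' @param n_only_A,n_only_B private reactions per source (half anchored to
#'   shared compounds, half floating).
#' @param synonym_perturbation_rate fraction of shared compounds whose
#'   synonym sets are disjoint variants across sources.
#' @param proton_discrepancy_rate fraction of shared reactions with explicit
#'   H+ and formula-proton discrepancies in source B.
#' @param cofactor_swap_rate fraction of ATP/ADP reactions duplicated with
#'   GTP/GDP in source A only.
#' @param generic_class_rate controls how many generic-class reactions
#'   source B carries.
#' @param structure_error_rate fraction of cross-referenced structured
#'   compounds whose source-B structure loses a functional group.
#' @param xref_seed_rate fraction of the non-classifier shared compounds
#'   carrying an explicit cross-reference in source B.
#' @param seed integer; the single source of randomness.
#' @return a list of class `gm_fixture_spec`.
#' @export
fixture_spec <- function(n_shared_reactions = 25, n_only_A = 5, n_only_B = 5,
                         synonym_perturbation_rate = 0.3,
                         proton_discrepancy_rate = 0.2,
                         cofactor_swap_rate = 0.15,
                         generic_class_rate = 0.1,
                         structure_error_rate = 0.1,
                         xref_seed_rate = 0.4,
                         seed = 42) {
  rates <- c(synonym_perturbation_rate, proton_discrepancy_rate,
             cofactor_swap_rate, generic_class_rate, structure_error_rate,
             xref_seed_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), n_shared_reactions >= 0,
            n_only_A >= 0, n_only_B >= 0)
  structure(list(n_shared_reactions = n_shared_reactions,
                 n_only_A = n_only_A, n_only_B = n_only_B,
                 synonym_perturbation_rate = synonym_perturbation_rate,
                 proton_discrepancy_rate = proton_discrepancy_rate,
                 cofactor_swap_rate = cofactor_swap_rate,
                 generic_class_rate = generic_class_rate,
                 structure_error_rate = structure_error_rate,
                 xref_seed_rate = xref_seed_rate, seed = seed),
            class = "gm_fixture_spec")
}

.icacid_variants <- function(synonyms) {
  norm <- normalize_name(synonyms)
  ate <- synonyms[endsWith(norm, "ate")]
  ic <- synonyms[endsWith(norm, "ic acid")]
  list(ate = ate, ic = ic)
}

.perturb_smiles <- function(s) {
  if (grepl("C(=O)O", s, fixed = TRUE)) {
    sub("C(=O)O", "C=O", s, fixed = TRUE)
  } else if (grepl("(O)", s, fixed = TRUE)) {
    sub("(O)", "", s, fixed = TRUE)
  } else {
    s
  }
}

#' Generate a pair of synthetic databases with ground truth
#'
#' @param spec a [fixture_spec()].
#' @return list with `dbA`, `dbB` ([source_db()] objects) and `truth`, a
#'   list holding `compound_pairs` (id_A, id_B, evidence_class),
#'   `reaction_pairs` (id_A, id_B) and `expected_tier` (named by
#'   `"A:<id>"`/`"B:<id>"`).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  tpl <- template_library()
  pool <- tpl$reactions
  n_shared <- spec$n_shared_reactions
  if (n_shared > nrow(pool)) {
    warning("template pool has only ", nrow(pool), " reactions; capping",
            call. = FALSE)
    n_shared <- nrow(pool)
  }
  with_seed(spec$seed, {
    shared_idx <- sort(sample(nrow(pool), n_shared))
    shared_rx <- pool[shared_idx, , drop = FALSE]
    parse_eq <- function(eq) parse_stoichiometry(eq)
    sides <- lapply(shared_rx$equation, parse_eq)
    shared_cp <- sort(unique(unlist(lapply(sides, function(s) {
      c(s$substrates$id, s$products$id)
    }))))

    # cofactor swaps need GTP/GDP records in both sources
    swap_targets <- which(vapply(sides, function(s) {
      ids <- c(s$substrates$id, s$products$id)
      all(c("C00002", "C00008") %in% ids)
    }, TRUE))
    do_swap <- swap_targets[stats::runif(length(swap_targets)) <
                              spec$cofactor_swap_rate]
    if (length(do_swap)) shared_cp <- union(shared_cp, c("C00044", "C00035"))

    n_generic <- min(2, round(spec$generic_class_rate * n_shared))
    if (n_generic >= 1) shared_cp <- union(shared_cp, c("C00003", "C00004"))
    if (n_generic >= 2) shared_cp <- union(shared_cp, c("C00006", "C00005"))
    shared_cp <- sort(shared_cp)

    # -- evidence class assignment -------------------------------------------
    rx_of <- lapply(stats::setNames(sides, shared_rx$id), function(s) {
      c(s$substrates$id, s$products$id)
    })
    classifier_load <- stats::setNames(integer(length(rx_of)), names(rx_of))
    evidence <- stats::setNames(rep("", length(shared_cp)), shared_cp)
    scan_order <- sample(shared_cp)
    for (id in scan_order) {
      row <- .tpl_row(id)
      v <- .icacid_variants(row$synonyms)
      eligible <- length(v$ate) > 0 && length(v$ic) > 0 && !row$is_generic &&
        !is.null(row$formula)
      hosts <- names(rx_of)[vapply(rx_of, function(p) id %in% p, TRUE)]
      room <- all(classifier_load[hosts] == 0)
      if (eligible && room &&
          stats::runif(1) < spec$synonym_perturbation_rate) {
        evidence[id] <- "classifier"
        classifier_load[hosts] <- classifier_load[hosts] + 1L
      }
    }
    rest <- shared_cp[evidence == ""]
    xref_pick <- rest[stats::runif(length(rest)) < spec$xref_seed_rate]
    evidence[xref_pick] <- "xref"
    evidence[evidence == ""] <- "synonym"
    if (!any(evidence %in% c("xref", "synonym"))) {
      warning("no seed matches planted; integration will stall", call. = FALSE)
    }

    cand <- names(evidence)[evidence == "xref"]
    cand <- cand[vapply(cand, function(id) !is.na(.tpl_row(id)$smiles), TRUE)]
    struct_err <- cand[stats::runif(length(cand)) < spec$structure_error_rate]
    # only count compounds whose structure actually admits a deletion edit
    struct_err <- struct_err[vapply(struct_err, function(id) {
      s <- .tpl_row(id)$smiles
      !identical(.perturb_smiles(s), s)
    }, TRUE)]

    # -- compound records ----------------------------------------------------
    b_id_of <- stats::setNames(sprintf("CPD-%04d", seq_along(shared_cp)),
                               shared_cp)
    cpsA <- list(); cpsB <- list()
    pairs <- data.frame(id_A = character(), id_B = character(),
                        evidence_class = character(), stringsAsFactors = FALSE)
    for (id in shared_cp) {
      row <- .tpl_row(id)
      ev <- evidence[[id]]
      namesA <- row$synonyms
      namesB <- row$synonyms
      xrefsA <- if (nzchar(row$chebi)) paste0("ChEBI:", sub("^CHEBI:", "", row$chebi)) else character()
      xrefsB <- character()
      smilesB <- row$smiles
      if (ev == "classifier") {
        v <- .icacid_variants(row$synonyms)
        namesA <- setdiff(row$synonyms, v$ic)
        namesB <- v$ic
        if (length(intersect(normalize_name(namesA), normalize_name(namesB)))) {
          ev <- "xref"   # safety: variants collide after normalization
          namesA <- row$synonyms; namesB <- row$synonyms
        }
        evidence[id] <- ev
      }
      if (ev == "xref") {
        xrefsB <- paste0("KEGG:", id)
      }
      if (ev == "synonym") {
        # shared preferred name, private tail synonyms
        k <- length(row$synonyms)
        namesB <- row$synonyms[seq_len(max(1, k - 1))]
      }
      if (id %in% struct_err && !is.na(smilesB)) {
        smilesB <- .perturb_smiles(smilesB)
      }
      cpsA[[id]] <- compound_record("A", id, namesA, row$formula, row$smiles,
                                    xrefsA, row$is_generic)
      cpsB[[id]] <- compound_record("B", b_id_of[[id]], namesB, row$formula,
                                    smilesB, xrefsB, row$is_generic)
      pairs <- rbind(pairs, data.frame(id_A = id, id_B = b_id_of[[id]],
                                       evidence_class = ev,
                                       stringsAsFactors = FALSE))
    }

    # -- shared reactions with planted proton discrepancies ------------------
    proton_rx <- names(rx_of)[stats::runif(length(rx_of)) <
                                spec$proton_discrepancy_rate]
    if (length(proton_rx)) {
      cpsB[["PROTON"]] <- compound_record("B", "PROTON", c("H+", "proton"),
                                          parse_formula("H"))
      # formula proton perturbation on one participant per proton reaction
      for (rid in proton_rx) {
        pid <- rx_of[[rid]][1]
        f <- cpsB[[pid]]$formula
        if (!is.null(f)) {
          f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + 1L
          cpsB[[pid]] <- compound_record("B", cpsB[[pid]]$source_id,
                                         cpsB[[pid]]$names, f,
                                         cpsB[[pid]]$smiles, cpsB[[pid]]$xrefs,
                                         cpsB[[pid]]$is_generic)
        }
      }
    }
    b_rid_of <- stats::setNames(sprintf("RXN-%04d", seq_len(nrow(shared_rx))),
                                shared_rx$id)
    rxsA <- list(); rxsB <- list()
    expected_tier <- character()
    rpairs <- data.frame(id_A = character(), id_B = character(),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(shared_rx))) {
      rid <- shared_rx$id[i]
      s <- sides[[i]]
      ec <- .split_field(shared_rx$ec[i], ";")
      rxsA[[rid]] <- reaction_record("A", rid, s$substrates, s$products, ec,
                                     pathways = shared_rx$pathway[i])
      subB <- s$substrates; prodB <- s$products
      subB$id <- unname(b_id_of[subB$id]); prodB$id <- unname(b_id_of[prodB$id])
      if (rid %in% proton_rx) {
        prodB <- rbind(prodB, data.frame(id = "PROTON", coef = 1))
      }
      bid <- b_rid_of[[rid]]
      rxsB[[bid]] <- reaction_record("B", bid, subB, prodB, ec,
                                     pathways = shared_rx$pathway[i])
      expected_tier[paste0("A:", rid)] <- "core"
      expected_tier[paste0("B:", bid)] <- "core"
      rpairs <- rbind(rpairs, data.frame(id_A = rid, id_B = bid,
                                         stringsAsFactors = FALSE))
    }

    # -- cofactor-swapped variants (source A only) ---------------------------
    existing_eqs <- vapply(shared_rx$equation, function(e) e, "")
    for (i in do_swap) {
      rid <- shared_rx$id[i]
      s <- sides[[i]]
      swp <- function(side) {
        side$id[side$id == "C00002"] <- "C00044"
        side$id[side$id == "C00008"] <- "C00035"
        side
      }
      sub2 <- swp(s$substrates); prod2 <- swp(s$products)
      eq2 <- format_stoichiometry(sub2, prod2)
      if (eq2 %in% existing_eqs) next
      rid2 <- paste0(rid, "G")
      rxsA[[rid2]] <- reaction_record("A", rid2, sub2, prod2,
                                      .split_field(shared_rx$ec[i], ";"),
                                      pathways = shared_rx$pathway[i])
      expected_tier[paste0("A:", rid2)] <- "intermediate"
    }

    # -- generic-class reactions (source B only) -----------------------------
    add_generic <- function(gen_sub, gen_prod, cof_sub, cof_prod, gid) {
      for (g in c(gen_sub, gen_prod)) {
        row <- .tpl_row(g)
        cpsB[[g]] <<- compound_record("B", paste0("CPD-", g), row$synonyms,
                                      NULL, NA_character_, character(), TRUE)
      }
      rxsB[[gid]] <<- reaction_record(
        "B", gid,
        data.frame(id = c(paste0("CPD-", gen_sub), b_id_of[[cof_sub]]), coef = 1),
        data.frame(id = c(paste0("CPD-", gen_prod), b_id_of[[cof_prod]]), coef = 1),
        "1.1.1.1")
      expected_tier[paste0("B:", gid)] <<- "complete"
    }
    if (n_generic >= 1) add_generic("C00069", "C00071", "C00003", "C00004", "RXN-GEN1")
    if (n_generic >= 2) add_generic("C62101", "C62102", "C00006", "C00005", "RXN-GEN2")

    # -- one-source-only reactions -------------------------------------------
    anchors <- names(evidence)[evidence == "xref"]
    anchors <- anchors[vapply(anchors, function(id) !is.na(.tpl_row(id)$smiles), TRUE)]
    if (!length(anchors)) {
      anchors <- shared_cp[vapply(shared_cp,
                                  function(id) !is.na(.tpl_row(id)$smiles), TRUE)]
    }
    anchors <- sample(anchors)
    add_private <- function(db_label, n, anchor_pool) {
      n_anch <- ceiling(n / 2)
      made <- 0; k <- 0
      while (made < n_anch && made < length(anchor_pool)) {
        made <- made + 1
        x <- anchor_pool[made]
        row <- .tpl_row(x)
        k <- k + 1
        if (db_label == "A") {
          uid <- sprintf("C9%03d", k); rid <- sprintf("R9%03d", k)
          cpsA[[uid]] <<- compound_record("A", uid, paste0("allo-", row$synonyms),
                                          row$formula, row$smiles)
          rxsA[[rid]] <<- reaction_record("A", rid,
                                          data.frame(id = x, coef = 1),
                                          data.frame(id = uid, coef = 1),
                                          sprintf("5.3.99.%d", k))
          expected_tier[paste0("A:", rid)] <<- "intermediate"
        } else {
          uid <- sprintf("CPD-9%03d", k); rid <- sprintf("RXN-9%03d", k)
          cpsB[[uid]] <<- compound_record("B", uid, paste0("threo-", row$synonyms),
                                          row$formula, row$smiles)
          rxsB[[rid]] <<- reaction_record("B", rid,
                                          data.frame(id = b_id_of[[x]], coef = 1),
                                          data.frame(id = uid, coef = 1),
                                          sprintf("5.3.99.%d", 50 + k))
          expected_tier[paste0("B:", rid)] <<- "intermediate"
        }
      }
      # floating pairs: two fresh compounds sharing a formula
      n_float <- n - made
      for (j in seq_len(n_float)) {
        row <- .tpl_row(sample(anchors, 1))
        if (db_label == "A") {
          u <- sprintf("C8%03d", j); v <- sprintf("C8%03d", j + 500)
          rid <- sprintf("R8%03d", j)
          cpsA[[u]] <<- compound_record("A", u, paste0("neo-", row$synonyms),
                                        row$formula, row$smiles)
          cpsA[[v]] <<- compound_record("A", v, paste0("iso-", row$synonyms),
                                        row$formula, row$smiles)
          rxsA[[rid]] <<- reaction_record("A", rid,
                                          data.frame(id = u, coef = 1),
                                          data.frame(id = v, coef = 1),
                                          sprintf("5.3.98.%d", j))
          expected_tier[paste0("A:", rid)] <<- "complete"
        } else {
          u <- sprintf("CPD-8%03d", j); v <- sprintf("CPD-8%03d", j + 500)
          rid <- sprintf("RXN-8%03d", j)
          cpsB[[u]] <<- compound_record("B", u, paste0("apo-", row$synonyms),
                                        row$formula, row$smiles)
          cpsB[[v]] <<- compound_record("B", v, paste0("epi-", row$synonyms),
                                        row$formula, row$smiles)
          rxsB[[rid]] <<- reaction_record("B", rid,
                                          data.frame(id = u, coef = 1),
                                          data.frame(id = v, coef = 1),
                                          sprintf("5.3.98.%d", 50 + j))
          expected_tier[paste0("B:", rid)] <<- "complete"
        }
      }
    }
    half <- ceiling(length(anchors) / 2)
    poolA <- anchors[seq_len(half)]
    poolB <- if (length(anchors) > half) anchors[(half + 1):length(anchors)] else anchors
    if (spec$n_only_A > 0) add_private("A", spec$n_only_A, poolA)
    if (spec$n_only_B > 0) add_private("B", spec$n_only_B, poolB)

    dbA <- source_db(unname(cpsA), unname(rxsA), "A")
    dbB <- source_db(unname(cpsB), unname(rxsB), "B")
    list(dbA = dbA, dbB = dbB,
         truth = list(compound_pairs = pairs, reaction_pairs = rpairs,
                      expected_tier = expected_tier, seed = spec$seed,
                      structure_errors = struct_err))
  })
}

#' Write a generated fixture to disk
#'
#' Emits `dbA/` and `dbB/` in the source dialect plus `ground_truth.tsv`;
#' file headers record the generating seed.
#'
#' @param fx result of [generate_fixture()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fx, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_source_db(fx$dbA, file.path(path, "dbA"))
  write_source_db(fx$dbB, file.path(path, "dbB"))
  for (d in c("dbA", "dbB")) {
    for (f in c("compounds.tsv", "reactions.tsv")) {
      p <- file.path(path, d, f)
      txt <- readLines(p, warn = FALSE)
      writeLines(c(sprintf("# synthetic fixture (seed %d)", fx$truth$seed), txt), p)
    }
  }
  gt <- fx$truth$compound_pairs
  utils::write.table(gt, file.path(path, "ground_truth_compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tiers <- data.frame(reaction = names(fx$truth$expected_tier),
                      expected_tier = unname(fx$truth$expected_tier),
                      stringsAsFactors = FALSE)
  utils::write.table(tiers, file.path(path, "ground_truth_tiers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Hand-coded fixtures for the canonical discrepancy cases and the
# tricarboxylic-acid / glyoxylate cycle comparison.

.mk_cp <- function(db, sid, tpl_id, names = NULL, xrefs = character(),
                   smiles = "tpl", generic = NA) {
  row <- .tpl_row(tpl_id)
  compound_record(db, sid,
                  names %||% row$synonyms,
                  if (isTRUE(generic)) NULL else row$formula,
                  if (identical(smiles, "tpl")) {
                    if (isTRUE(generic)) NA_character_ else row$smiles
                  } else smiles,
                  xrefs,
                  if (is.na(generic)) row$is_generic else generic)
}

.side <- function(...) {
  v <- c(...)
  data.frame(id = names(v), coef = as.numeric(v), stringsAsFactors = FALSE)
}

#' Fixture encoding the six canonical cross-database discrepancy cases
#'
#' Two small databases containing (a) an identically described reaction,
#' (b) a reaction differing only in explicit protons, (c) a cofactor variant
#' (GTP/GDP) known to one source, (d) a private two-step activation route
#' anchored in well-known compounds, (e) a private reaction whose substrate
#' and product are both unknown to the other source, and (f) a generic-class
#' reaction.  Expected tiers: core, core, intermediate, intermediate,
#' complete, complete.
#'
#' @return list with `dbA`, `dbB`, `truth` (`expected_tier` named by
#'   `"A:<id>"`/`"B:<id>"`, and `cases` mapping case labels to reaction
#'   keys).
#' @export
discrepancy_fixture <- function() {
  shared <- c("C02591", "C00001", "C00089", "C00009", "C01182", "C00011",
              "C00197", "C00074", "C00035", "C00044", "C00022", "C00008",
              "C00002", "C00033", "C00020", "C00013", "C00010", "C00024",
              "C00003", "C00004", "C00014")
  b_of <- stats::setNames(sprintf("CPD-%04d", seq_along(shared)), shared)
  cpsA <- lapply(shared, function(id) .mk_cp("A", id, id))
  cpsB <- lapply(shared, function(id) {
    .mk_cp("B", b_of[[id]], id, xrefs = paste0("KEGG:", id))
  })
  # A-only compounds
  cpsA <- c(cpsA, list(
    .mk_cp("A", "C00080", "C00080"),                       # free protons
    .mk_cp("A", "C05993", "C05993"),                       # acetyl adenylate
    .mk_cp("A", "C00542", "C00542"),                       # cystathionine
    .mk_cp("A", "C05330", "C05330")                        # homocysteine
  ))
  # B-only generic classes
  cpsB <- c(cpsB, list(
    .mk_cp("B", "ALCOHOLS", "C00069", generic = TRUE),
    .mk_cp("B", "ALDEHYDES", "C00071", generic = TRUE)
  ))
  B <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v),
                    ifelse(names(v) %in% names(b_of), b_of[names(v)], names(v)))
  }
  rxsA <- list(
    reaction_record("A", "R00803", .side(C02591 = 1, C00001 = 1),
                    .side(C00089 = 1, C00009 = 1), "3.1.3.24"),
    reaction_record("A", "R00024", .side(C01182 = 1, C00011 = 1, C00001 = 1),
                    .side(C00197 = 2, C00080 = 2), "4.1.1.39"),
    reaction_record("A", "R00200", .side(C00074 = 1, C00008 = 1),
                    .side(C00022 = 1, C00002 = 1), "2.7.1.40"),
    reaction_record("A", "R01195", .side(C00074 = 1, C00035 = 1),
                    .side(C00022 = 1, C00044 = 1), "2.7.1.40"),
    reaction_record("A", "R00235", .side(C00033 = 1, C00002 = 1),
                    .side(C05993 = 1, C00013 = 1), "6.2.1.1"),
    reaction_record("A", "R00236", .side(C05993 = 1, C00010 = 1),
                    .side(C00024 = 1, C00020 = 1), "6.2.1.1"),
    reaction_record("A", "R01286", .side(C00542 = 1, C00001 = 1),
                    .side(C05330 = 1, C00022 = 1, C00014 = 1), "4.4.1.8")
  )
  rxsB <- list(
    reaction_record("B", "RXN-0001", .side(B(C02591 = 1, C00001 = 1)),
                    .side(B(C00089 = 1, C00009 = 1)), "3.1.3.24"),
    reaction_record("B", "RXN-0002", .side(B(C01182 = 1, C00011 = 1, C00001 = 1)),
                    .side(B(C00197 = 2)), "4.1.1.39"),
    reaction_record("B", "RXN-0003", .side(B(C00074 = 1, C00008 = 1)),
                    .side(B(C00022 = 1, C00002 = 1)), "2.7.1.40"),
    reaction_record("B", "RXN-0004",
                    .side(ALCOHOLS = 1, "CPD-0019" = 1),
                    .side(ALDEHYDES = 1, "CPD-0020" = 1), "1.1.1.1")
  )
  dbA <- source_db(cpsA, rxsA, "A")
  dbB <- source_db(cpsB, rxsB, "B")
  expected_tier <- c(
    "A:R00803" = "core", "B:RXN-0001" = "core",
    "A:R00024" = "core", "B:RXN-0002" = "core",
    "A:R00200" = "core", "B:RXN-0003" = "core",
    "A:R01195" = "intermediate",
    "A:R00235" = "intermediate", "A:R00236" = "intermediate",
    "A:R01286" = "complete",
    "B:RXN-0004" = "complete"
  )
  cases <- list(identical = "A:R00803", proton = "A:R00024",
                cofactor = "A:R01195", one_source_anchored = "A:R00236",
                one_source_floating = "A:R01286", generic_class = "B:RXN-0004")
  list(dbA = dbA, dbB = dbB,
       truth = list(expected_tier = expected_tier, cases = cases))
}

#' Two-database fixture of the tricarboxylic-acid and glyoxylate cycles
#'
#' Encodes the published cross-database comparison of the cycle: most
#' reactions are described identically in both sources and reach the core
#' tier; succinate dehydrogenase suffers a generic-vs-specific ubiquinone
#' ambiguity; the direct ketoglutarate dehydrogenase reaction is private to
#' source B while source A details the three-step route via
#' 3-carboxy-1-hydroxypropyl-ThPP and succinyldihydrolipoamide-E; the
#' oxalosuccinate route of isocitrate oxidation is private to source A.
#'
#' @return list with `dbA`, `dbB`, `truth` as in [discrepancy_fixture()].
#' @export
tca_fixture <- function() {
  # compounds present in both sources (cross-referenced unless noted)
  xref_cp <- c("C00042", "C00122", "C00001", "C00149", "C00003", "C00004",
               "C00006", "C00005", "C00008", "C00009", "C00024", "C00158",
               "C00311", "C00026", "C00011", "C00091", "C00010", "C00002",
               "C00035", "C00044", "C00068")
  b_of <- stats::setNames(sprintf("CPD-%04d", seq_along(xref_cp)), xref_cp)
  cpsA <- lapply(xref_cp, function(id) .mk_cp("A", id, id))
  cpsB <- lapply(xref_cp, function(id) {
    .mk_cp("B", b_of[[id]], id, xrefs = paste0("KEGG:", id))
  })
  # shared by synonym only
  cpsA <- c(cpsA, list(.mk_cp("A", "C00417", "C00417"),
                       .mk_cp("A", "C00048", "C00048")))
  cpsB <- c(cpsB, list(.mk_cp("B", "CIS-ACONITATE", "C00417"),
                       .mk_cp("B", "GLYOX", "C00048")))
  b_of["C00417"] <- "CIS-ACONITATE"; b_of["C00048"] <- "GLYOX"
  # oxaloacetate: recoverable only through reaction context + name model
  oaa <- .tpl_row("C00036")
  cpsA <- c(cpsA, list(compound_record("A", "C00036",
                                       c("oxaloacetate", "2-oxosuccinate"),
                                       oaa$formula, oaa$smiles)))
  cpsB <- c(cpsB, list(compound_record("B", "OAA",
                                       c("oxaloacetic acid", "oxalacetic acid"),
                                       oaa$formula, oaa$smiles)))
  b_of["C00036"] <- "OAA"
  # ubiquinone: generic class in A, specific in B (cross-referenced to the
  # generic); ubiquinol stays ambiguous in both
  cpsA <- c(cpsA, list(.mk_cp("A", "C00399", "C00399", generic = TRUE),
                       .mk_cp("A", "C00390", "C00390", generic = TRUE)))
  cpsB <- c(cpsB, list(.mk_cp("B", "UBIQUINONE-8", "C17569",
                              xrefs = "KEGG:C00399"),
                       .mk_cp("B", "UBIQUINOL-8", "C17570")))
  # A-only compounds of the three-step route, plus oxalosuccinate
  cpsA <- c(cpsA, list(.mk_cp("A", "C05379", "C05379"),
                       .mk_cp("A", "C05125", "C05125"),
                       .mk_cp("A", "C15972", "C15972"),
                       .mk_cp("A", "C15973", "C15973"),
                       .mk_cp("A", "C16254", "C16254")))
  B <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), unname(b_of[names(v)]))
  }
  shared_eqs <- list(
    # id suffixes, substrates, products, ec
    list("02", .side(C00122 = 1, C00001 = 1), .side(C00149 = 1), "4.2.1.2"),
    list("03", .side(C00149 = 1, C00003 = 1), .side(C00036 = 1, C00004 = 1), "1.1.1.37"),
    list("04", .side(C00149 = 1, C00006 = 1), .side(C00036 = 1, C00005 = 1), "1.1.1.82"),
    list("05", .side(C00036 = 1, C00008 = 1, C00009 = 1, C00024 = 1),
         .side(C00158 = 1, C00002 = 1, C00010 = 1), "2.3.3.8"),
    list("06", .side(C00158 = 1), .side(C00417 = 1, C00001 = 1), "4.2.1.3"),
    list("07", .side(C00417 = 1, C00001 = 1), .side(C00311 = 1), "4.2.1.3"),
    list("08", .side(C00311 = 1), .side(C00042 = 1, C00048 = 1), "4.1.3.1"),
    list("09", .side(C00048 = 1, C00001 = 1, C00024 = 1),
         .side(C00149 = 1, C00010 = 1), "2.3.3.9"),
    list("10", .side(C00311 = 1, C00003 = 1),
         .side(C00026 = 1, C00011 = 1, C00004 = 1), "1.1.1.41"),
    list("11", .side(C00311 = 1, C00006 = 1),
         .side(C00026 = 1, C00011 = 1, C00005 = 1), "1.1.1.42"),
    list("18", .side(C00091 = 1, C00008 = 1, C00009 = 1),
         .side(C00042 = 1, C00002 = 1, C00010 = 1), "6.2.1.5"),
    list("19", .side(C00091 = 1, C00035 = 1, C00009 = 1),
         .side(C00042 = 1, C00044 = 1, C00010 = 1), "6.2.1.4")
  )
  rxsA <- list(); rxsB <- list()
  expected_tier <- character()
  for (e in shared_eqs) {
    ridA <- paste0("TCA", e[[1]]); ridB <- paste0("RXN-TCA", e[[1]])
    rxsA[[ridA]] <- reaction_record("A", ridA, e[[2]], e[[3]], e[[4]],
                                    pathways = "tca")
    sB <- e[[2]]; pB <- e[[3]]
    sB$id <- unname(b_of[sB$id]); pB$id <- unname(b_of[pB$id])
    rxsB[[ridB]] <- reaction_record("B", ridB, sB, pB, e[[4]],
                                    pathways = "tca")
    expected_tier[paste0("A:", ridA)] <- "core"
    expected_tier[paste0("B:", ridB)] <- "core"
  }
  # succinate dehydrogenase: generic quinones in A, specific in B
  rxsA[["TCA01"]] <- reaction_record("A", "TCA01",
                                     .side(C00042 = 1, C00399 = 1),
                                     .side(C00122 = 1, C00390 = 1), "1.3.5.1",
                                     pathways = "tca")
  rxsB[["RXN-TCA01"]] <- reaction_record("B", "RXN-TCA01",
                                         .side(B(C00042 = 1), "UBIQUINONE-8" = 1),
                                         .side(B(C00122 = 1), "UBIQUINOL-8" = 1),
                                         "1.3.5.1", pathways = "tca")
  expected_tier["A:TCA01"] <- "intermediate"
  expected_tier["B:RXN-TCA01"] <- "intermediate"
  # direct ketoglutarate dehydrogenase: source B only
  rxsB[["RXN-KGDH"]] <- reaction_record("B", "RXN-KGDH",
                                        .side(B(C00026 = 1, C00010 = 1, C00003 = 1)),
                                        .side(B(C00091 = 1, C00011 = 1, C00004 = 1)),
                                        "1.2.4.2", pathways = "tca")
  expected_tier["B:RXN-KGDH"] <- "intermediate"
  # three-step route: source A only
  rxsA[["TCA15"]] <- reaction_record("A", "TCA15",
                                     .side(C00026 = 1, C00068 = 1),
                                     .side(C05125 = 1, C00011 = 1), "1.2.4.2",
                                     pathways = "tca")
  rxsA[["TCA16"]] <- reaction_record("A", "TCA16",
                                     .side(C05125 = 1, C15972 = 1),
                                     .side(C16254 = 1, C00068 = 1), "1.2.4.2",
                                     pathways = "tca")
  rxsA[["TCA17"]] <- reaction_record("A", "TCA17",
                                     .side(C16254 = 1, C00010 = 1),
                                     .side(C00091 = 1, C15973 = 1), "2.3.1.61",
                                     pathways = "tca")
  expected_tier["A:TCA15"] <- "intermediate"
  expected_tier["A:TCA16"] <- "complete"
  expected_tier["A:TCA17"] <- "complete"
  # oxalosuccinate route: source A only
  rxsA[["TCA12"]] <- reaction_record("A", "TCA12",
                                     .side(C00311 = 1, C00006 = 1),
                                     .side(C05379 = 1, C00005 = 1), "1.1.1.42",
                                     pathways = "tca")
  rxsA[["TCA13"]] <- reaction_record("A", "TCA13",
                                     .side(C05379 = 1, C00006 = 1),
                                     .side(C00026 = 1, C00011 = 1, C00005 = 1),
                                     "1.1.1.42", pathways = "tca")
  expected_tier["A:TCA12"] <- "intermediate"
  expected_tier["A:TCA13"] <- "intermediate"
  dbA <- source_db(unname(cpsA), unname(rxsA), "A")
  dbB <- source_db(unname(cpsB), unname(rxsB), "B")
  list(dbA = dbA, dbB = dbB, truth = list(expected_tier = expected_tier))
}
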