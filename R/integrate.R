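# Iterative cross-database matching engine and tier assignment.
#
# Workflow: (1) seed compound matches from explicit cross-references and
# exact shared synonyms; (2) repeatedly scan reaction pairs -- a pair whose
# participants all map with equal coefficients (and compatible enzymes) is a
# matched reaction; a pair that agrees on everything except exactly one
# participant per corresponding side nominates that participant pair as a
# candidate identity, accepted when enzyme, name-similarity and
# structure/formula evidence all concur; (3) iterate until a fixpoint, with
# partially-supported candidates queued for manual review (decisions can be
# injected between runs); (4) assign the three confidence tiers.
#
# Free protons are never represented: there is no pH consistency between
# databases, so protons are removed from every reaction side before any
# comparison and from all outputs, and proton-count differences between
# formulae are ignored.

.proton_name_allowlist <- c("h+", "proton", "hydron")
.proton_id_allowlist <- c("C00080", "PROTON", "HPLUS")

.is_proton <- function(cp) {
  cp$source_id %in% .proton_id_allowlist ||
    any(normalize_name(cp$names) %in% .proton_name_allowlist) ||
    any(toupper(sub("^[^:]+:", "", cp$xrefs)) == "C00080")
}

.proton_ids <- function(db, extra = character()) {
  ids <- names(db$compounds)[vapply(db$compounds, .is_proton, TRUE)]
  union(ids, extra)
}

.drop_protons <- function(side, proton_ids) {
  side[!side$id %in% proton_ids, , drop = FALSE]
}

#' Integration configuration
#'
#' @param name_threshold minimum name-similarity probability for automatic
#'   acceptance (default 0.9); pairs scoring in `[0.5, name_threshold)` count
#'   as partial evidence and reach the review queue.
#' @param tanimoto_threshold fingerprint similarity above which two distinct
#'   structures are flagged as near matches (default 0.8); never sufficient
#'   for automatic acceptance.
#' @param negatives_per_positive negative sampling ratio for name-model
#'   training.
#' @param seed integer seed for all randomized steps.
#' @param proton_ids extra compound ids to treat as free protons.
#' @param id_prefix prefix for local identifiers (compounds
#'   `<prefix>C0001`..., reactions `<prefix>R0001`...).
#' @param max_iterations safety cap on propagation iterations.
#' @return a list of class `gm_config`.
#' @export
integration_config <- function(name_threshold = 0.9, tanimoto_threshold = 0.8,
                               negatives_per_positive = 1, seed = 1,
                               proton_ids = character(), id_prefix = "Ath_",
                               max_iterations = 50) {
  stopifnot(name_threshold >= 0, name_threshold <= 1,
            tanimoto_threshold >= 0, tanimoto_threshold <= 1)
  structure(list(name_threshold = name_threshold,
                 tanimoto_threshold = tanimoto_threshold,
                 negatives_per_positive = negatives_per_positive,
                 seed = seed, proton_ids = proton_ids,
                 id_prefix = id_prefix, max_iterations = max_iterations),
            class = "gm_config")
}

#' Read a key=value configuration file
#'
#' Recognized keys mirror the arguments of [integration_config()]; unknown
#' keys raise an error.  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a `gm_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = "="))
    args[[key]] <- switch(key,
      name_threshold = , tanimoto_threshold = ,
      negatives_per_positive = as.numeric(val),
      seed = , max_iterations = as.integer(val),
      proton_ids = strsplit(val, ",", fixed = TRUE)[[1]],
      id_prefix = val,
      stop_gm("unknown configuration key: ", key)
    )
  }
  do.call(integration_config, args)
}

.empty_cmatch <- function() {
  data.frame(id_A = character(), id_B = character(), evidence = character(),
             name_probability = numeric(), structure_tier = character(),
             stringsAsFactors = FALSE)
}

.empty_review <- function() {
  data.frame(id_A = character(), id_B = character(), ec_ok = logical(),
             name_ok = logical(), struct_ok = logical(),
             name_probability = numeric(), structure_tier = character(),
             note = character(), stringsAsFactors = FALSE)
}

#' Seed the match state from cross-references and shared synonyms
#'
#' Compounds are paired when one record's cross-references contain the
#' other's source id, when both records share an identical
#' namespace-qualified cross-reference, or when their normalized synonym
#' sets intersect.  A compound claiming two distinct partners through such
#' evidence is not auto-matched: all its candidate pairs go to the review
#' queue instead (the matching must stay injective).
#'
#' @param dbA,dbB `gm_source_db` objects (labels A and B).
#' @param config a [integration_config()].
#' @return a list of class `gm_match_state`.
#' @export
seed_matches <- function(dbA, dbB, config = integration_config()) {
  protA <- .proton_ids(dbA, config$proton_ids)
  protB <- .proton_ids(dbB, config$proton_ids)
  idsA <- setdiff(names(dbA$compounds), protA)
  idsB <- setdiff(names(dbB$compounds), protB)
  xref_ids <- function(cp) toupper(sub("^[^:]+:", "", cp$xrefs))
  xr_A <- lapply(dbA$compounds, xref_ids)
  xr_B <- lapply(dbB$compounds, xref_ids)
  full_A <- lapply(dbA$compounds, function(cp) toupper(cp$xrefs))
  full_B <- lapply(dbB$compounds, function(cp) toupper(cp$xrefs))
  syn_A <- lapply(dbA$compounds, function(cp) unique(normalize_name(cp$names)))
  syn_B <- lapply(dbB$compounds, function(cp) unique(normalize_name(cp$names)))

  edges <- list()
  for (a in idsA) {
    for (b in idsB) {
      xref_hit <- toupper(b) %in% xr_A[[a]] || toupper(a) %in% xr_B[[b]] ||
        length(intersect(full_A[[a]], full_B[[b]])) > 0
      if (xref_hit) {
        edges[[length(edges) + 1]] <- data.frame(
          id_A = a, id_B = b, evidence = "seed_xref", stringsAsFactors = FALSE)
        next
      }
      if (length(intersect(syn_A[[a]], syn_B[[b]]))) {
        edges[[length(edges) + 1]] <- data.frame(
          id_A = a, id_B = b, evidence = "exact_synonym",
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(id_A = character(), id_B = character(),
               evidence = character(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$evidence != "seed_xref", edges$id_A, edges$id_B), ,
                 drop = FALSE]
  cmatch <- .empty_cmatch()
  review <- .empty_review()
  # xref edges first, then synonym edges; any multiplicity -> review
  for (ev in c("seed_xref", "exact_synonym")) {
    sub <- edges[edges$evidence == ev &
                   !edges$id_A %in% cmatch$id_A &
                   !edges$id_B %in% cmatch$id_B, , drop = FALSE]
    if (!nrow(sub)) next
    conflicted <- unique(c(sub$id_A[duplicated(sub$id_A)],
                           sub$id_B[duplicated(sub$id_B)]))
    bad <- sub$id_A %in% conflicted | sub$id_B %in% conflicted
    for (i in which(bad)) {
      review <- rbind(review, data.frame(
        id_A = sub$id_A[i], id_B = sub$id_B[i], ec_ok = NA, name_ok = NA,
        struct_ok = NA, name_probability = NA_real_,
        structure_tier = NA_character_,
        note = paste0("ambiguous ", ev, " (one-to-many)"),
        stringsAsFactors = FALSE))
    }
    ok <- sub[!bad, , drop = FALSE]
    if (nrow(ok)) {
      cmatch <- rbind(cmatch, data.frame(
        id_A = ok$id_A, id_B = ok$id_B, evidence = ok$evidence,
        name_probability = NA_real_, structure_tier = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(cmatch = cmatch,
                 rmatch = data.frame(id_A = character(), id_B = character(),
                                     stringsAsFactors = FALSE),
                 review = review, iteration = 0L,
                 log = data.frame(iteration = integer(),
                                  new_compounds = integer(),
                                  new_reactions = integer()),
                 protons_A = protA, protons_B = protB),
            class = "gm_match_state")
}

#' @export
print.gm_match_state <- function(x, ...) {
  cat(sprintf(paste0("<match state: %d compound pairs, %d reaction pairs, ",
                     "%d in review, %d iteration(s)>\n"),
              nrow(x$cmatch), nrow(x$rmatch), nrow(x$review), x$iteration))
  invisible(x)
}

# match one reaction side against another through the A->B compound map;
# returns leftover participant rows of each side, or NULL if structurally
# impossible (coefficient mismatch on a mapped compound).
.match_side <- function(sA, sB, map_AB) {
  usedB <- rep(FALSE, nrow(sB))
  leftA <- integer()
  for (i in seq_len(nrow(sA))) {
    b_id <- map_AB[[sA$id[i]]]
    hit <- 0
    if (!is.null(b_id)) {
      for (j in seq_len(nrow(sB))) {
        if (!usedB[j] && sB$id[j] == b_id && sB$coef[j] == sA$coef[i]) {
          hit <- j; break
        }
      }
    }
    if (hit > 0) usedB[hit] <- TRUE else leftA <- c(leftA, i)
  }
  list(left_A = sA[leftA, , drop = FALSE],
       left_B = sB[!usedB, , drop = FALSE])
}

#' Compare two reactions under the current compound matching
#'
#' Free protons are removed from both sides first.  Both orientations of the
#' second reaction are tried (directionality is ignored during matching).
#' The outcome is `full_match` when all participants map one-to-one with
#' equal coefficients and the EC sets are compatible; `one_unknown` when
#' participant counts agree, every participant maps except exactly one on
#' corresponding sides of each reaction (with equal coefficients), in which
#' case the unmatched pair is nominated as a candidate identity; otherwise
#' `incompatible`.
#'
#' @param rA,rB `gm_reaction` records from databases A and B.
#' @param state a `gm_match_state`.
#' @return list with `status` and, for `one_unknown`, `candidate`
#'   (`id_A`, `id_B`, and the EC sets of both reactions).
#' @export
compare_reactions <- function(rA, rB, state) {
  map_AB <- stats::setNames(as.list(state$cmatch$id_B), state$cmatch$id_A)
  sA <- .drop_protons(rA$substrates, state$protons_A)
  pA <- .drop_protons(rA$products, state$protons_A)
  sB <- .drop_protons(rB$substrates, state$protons_B)
  pB <- .drop_protons(rB$products, state$protons_B)
  if (!nrow(sA) || !nrow(pA) || !nrow(sB) || !nrow(pB)) {
    return(list(status = "incompatible"))
  }
  ec_compatible <- !length(rA$ec) || !length(rB$ec) ||
    length(intersect(rA$ec, rB$ec)) > 0
  best <- list(status = "incompatible")
  rank <- c(incompatible = 0, one_unknown = 1, full_match = 2)
  for (orient in 1:2) {
    bS <- if (orient == 1) sB else pB
    bP <- if (orient == 1) pB else sB
    if (nrow(sA) != nrow(bS) || nrow(pA) != nrow(bP)) next
    ms <- .match_side(sA, bS, map_AB)
    mp <- .match_side(pA, bP, map_AB)
    n_left <- nrow(ms$left_A) + nrow(mp$left_A)
    res <- if (n_left == 0 && nrow(ms$left_B) + nrow(mp$left_B) == 0) {
      if (ec_compatible) list(status = "full_match") else
        list(status = "incompatible")
    } else if (n_left == 1 && nrow(ms$left_B) + nrow(mp$left_B) == 1) {
      la <- rbind(ms$left_A, mp$left_A)
      lb <- rbind(ms$left_B, mp$left_B)
      same_side <- (nrow(ms$left_A) == 1) == (nrow(ms$left_B) == 1)
      unmatched_A <- !la$id %in% state$cmatch$id_A
      unmatched_B <- !lb$id %in% state$cmatch$id_B
      if (same_side && la$coef == lb$coef && unmatched_A && unmatched_B) {
        list(status = "one_unknown",
             candidate = list(id_A = la$id, id_B = lb$id,
                              ec_A = rA$ec, ec_B = rB$ec))
      } else {
        list(status = "incompatible")
      }
    } else {
      list(status = "incompatible")
    }
    if (rank[[res$status]] > rank[[best$status]]) best <- res
  }
  best
}

.ec_full_level <- function(ec) ec[grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)]

#' Decide the fate of a candidate compound pair
#'
#' Acceptance demands the conjunction of three pieces of evidence: the two
#' host reactions share an EC number at full four-level precision; the best
#' name-pair similarity reaches the acceptance threshold; and the structures
#' match exactly (or, when either compound has no structure, the formulas
#' agree outside hydrogen).  Pairs supported by some but not all evidence go
#' to manual review; pairs supported by none are rejected.
#'
#' @param candidate list with `id_A`, `id_B`, `ec_A`, `ec_B` (from
#'   [compare_reactions()]).
#' @param dbA,dbB source databases.
#' @param name_model a trained `gm_name_model`.
#' @param config a [integration_config()].
#' @param forms_A,forms_B optional precomputed [structure_forms()] lists
#'   keyed by source id (computed on demand when absent).
#' @return list with `decision` (`"accept"`, `"review"`, `"reject"`) and the
#'   evidence fields (`ec_ok`, `name_ok`, `struct_ok`, `name_probability`,
#'   `structure_tier`).
#' @export
accept_candidate <- function(candidate, dbA, dbB, name_model,
                             config = integration_config(),
                             forms_A = NULL, forms_B = NULL) {
  ca <- dbA$compounds[[candidate$id_A]]
  cb <- dbB$compounds[[candidate$id_B]]
  ec_ok <- length(intersect(.ec_full_level(candidate$ec_A),
                            .ec_full_level(candidate$ec_B))) > 0
  grid <- expand.grid(a = ca$names, b = cb$names, stringsAsFactors = FALSE)
  prob <- max(score_names(name_model, grid$a, grid$b))
  name_ok <- prob >= config$name_threshold
  has_sa <- !is.na(ca$smiles); has_sb <- !is.na(cb$smiles)
  if (has_sa && has_sb) {
    fa <- forms_A[[candidate$id_A]] %||% structure_forms(ca$smiles)
    fb <- forms_B[[candidate$id_B]] %||% structure_forms(cb$smiles)
    sm <- match_structures(fa, fb, config$tanimoto_threshold)
    struct_tier <- sm$tier
    struct_ok <- identical(sm$tier, "exact")
  } else if (formula_equal_ignoring_h(ca$formula, cb$formula)) {
    struct_tier <- "formula_only"
    struct_ok <- TRUE
  } else {
    struct_tier <- "none"
    struct_ok <- FALSE
  }
  n_pass <- sum(ec_ok, name_ok, struct_ok)
  decision <- if (n_pass == 3) "accept" else if (n_pass >= 1) "review" else "reject"
  list(decision = decision, ec_ok = ec_ok, name_ok = name_ok,
       struct_ok = struct_ok, name_probability = prob,
       structure_tier = struct_tier)
}

#' Run the iterative integration to its fixpoint
#'
#' Starting from the seed matching, repeatedly scans all unmatched reaction
#' pairs, records full matches, evaluates single-unknown candidates, and
#' adds accepted compound identities; iteration stops when nothing new is
#' found.  Candidate pairs with partial evidence accumulate in the review
#' queue; externally resolved decisions can be injected to improve the next
#' run.
#'
#' @param dbA,dbB source databases.
#' @param name_model trained `gm_name_model` (see [train_name_model()]); if
#'   `NULL`, one is trained on the pooled synonym sets of both databases.
#' @param config a [integration_config()].
#' @param review_decisions optional data.frame with columns `id_A`, `id_B`,
#'   `decision` (`"accept"`/`"reject"`): resolved review-queue entries
#'   applied before the first iteration.
#' @return a `gm_match_state` at fixpoint.
#' @export
integrate_databases <- function(dbA, dbB, name_model = NULL,
                                config = integration_config(),
                                review_decisions = NULL) {
  if (is.null(name_model)) {
    pairs <- build_training_set(list(dbA, dbB),
                                negatives_per_positive = config$negatives_per_positive,
                                seed = config$seed)
    name_model <- train_name_model(pairs, threshold = config$name_threshold)
  }
  state <- seed_matches(dbA, dbB, config)
  if (!is.null(review_decisions) && nrow(review_decisions)) {
    acc <- review_decisions[review_decisions$decision == "accept", , drop = FALSE]
    for (i in seq_len(nrow(acc))) {
      if (acc$id_A[i] %in% state$cmatch$id_A ||
          acc$id_B[i] %in% state$cmatch$id_B) {
        existing <- state$cmatch[state$cmatch$id_A == acc$id_A[i] |
                                   state$cmatch$id_B == acc$id_B[i], ]
        if (!any(existing$id_A == acc$id_A[i] & existing$id_B == acc$id_B[i])) {
          stop_gm("injected review decision ", acc$id_A[i], " <-> ",
                  acc$id_B[i], " conflicts with the injective matching")
        }
      } else {
        state$cmatch <- rbind(state$cmatch, data.frame(
          id_A = acc$id_A[i], id_B = acc$id_B[i], evidence = "manual",
          name_probability = NA_real_, structure_tier = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }
  # structure forms computed once per database
  smiA <- vapply(dbA$compounds, `[[`, "", "smiles")
  smiB <- vapply(dbB$compounds, `[[`, "", "smiles")
  forms_A <- stats::setNames(structure_forms(smiA), names(dbA$compounds))
  forms_B <- stats::setNames(structure_forms(smiB), names(dbB$compounds))
  if (length(smiA) == 1) forms_A <- stats::setNames(list(forms_A), names(dbA$compounds))
  if (length(smiB) == 1) forms_B <- stats::setNames(list(forms_B), names(dbB$compounds))

  rxA <- dbA$reactions[order(names(dbA$reactions))]
  rxB <- dbB$reactions[order(names(dbB$reactions))]
  repeat {
    state$iteration <- state$iteration + 1L
    if (state$iteration > config$max_iterations) {
      warning("iteration cap reached before fixpoint", call. = FALSE)
      break
    }
    freeA <- setdiff(names(rxA), state$rmatch$id_A)
    freeB <- setdiff(names(rxB), state$rmatch$id_B)
    new_rx <- data.frame(id_A = character(), id_B = character(),
                         stringsAsFactors = FALSE)
    cand_rows <- list()
    for (a in freeA) {
      for (b in freeB) {
        res <- compare_reactions(rxA[[a]], rxB[[b]], state)
        if (res$status == "full_match") {
          if (!a %in% new_rx$id_A && !b %in% new_rx$id_B) {
            new_rx <- rbind(new_rx, data.frame(id_A = a, id_B = b,
                                               stringsAsFactors = FALSE))
          }
        } else if (res$status == "one_unknown") {
          cand_rows[[length(cand_rows) + 1]] <- res$candidate
        }
      }
    }
    # evaluate candidates (dedup by compound pair, pooling host-reaction ECs)
    accepted <- .empty_cmatch()
    if (length(cand_rows)) {
      keys <- vapply(cand_rows, function(cd) paste(cd$id_A, cd$id_B, sep = "\r"), "")
      for (key in unique(keys)) {
        grp <- cand_rows[keys == key]
        cd <- grp[[1]]
        cd$ec_A <- unique(unlist(lapply(grp, `[[`, "ec_A")))
        cd$ec_B <- unique(unlist(lapply(grp, `[[`, "ec_B")))
        verdict <- accept_candidate(cd, dbA, dbB, name_model, config,
                                    forms_A, forms_B)
        if (verdict$decision == "accept") {
          accepted <- rbind(accepted, data.frame(
            id_A = cd$id_A, id_B = cd$id_B, evidence = "classifier_plus_structure",
            name_probability = verdict$name_probability,
            structure_tier = verdict$structure_tier, stringsAsFactors = FALSE))
        } else if (verdict$decision == "review") {
          already <- any(state$review$id_A == cd$id_A &
                           state$review$id_B == cd$id_B)
          if (!already) {
            state$review <- rbind(state$review, data.frame(
              id_A = cd$id_A, id_B = cd$id_B, ec_ok = verdict$ec_ok,
              name_ok = verdict$name_ok, struct_ok = verdict$struct_ok,
              name_probability = verdict$name_probability,
              structure_tier = verdict$structure_tier,
              note = "partial evidence from reaction context",
              stringsAsFactors = FALSE))
          }
        }
      }
    }
    if (nrow(accepted)) {
      accepted <- accepted[order(accepted$id_A, accepted$id_B), , drop = FALSE]
      conflicted <- unique(c(accepted$id_A[duplicated(accepted$id_A)],
                             accepted$id_B[duplicated(accepted$id_B)]))
      bad <- accepted$id_A %in% conflicted | accepted$id_B %in% conflicted
      for (i in which(bad)) {
        state$review <- rbind(state$review, data.frame(
          id_A = accepted$id_A[i], id_B = accepted$id_B[i], ec_ok = TRUE,
          name_ok = TRUE, struct_ok = TRUE,
          name_probability = accepted$name_probability[i],
          structure_tier = accepted$structure_tier[i],
          note = "acceptance conflict (one-to-many in same iteration)",
          stringsAsFactors = FALSE))
      }
      accepted <- accepted[!bad, , drop = FALSE]
      accepted <- accepted[!accepted$id_A %in% state$cmatch$id_A &
                             !accepted$id_B %in% state$cmatch$id_B, , drop = FALSE]
      state$cmatch <- rbind(state$cmatch, accepted)
    }
    if (nrow(new_rx)) state$rmatch <- rbind(state$rmatch, new_rx)
    state$log <- rbind(state$log, data.frame(
      iteration = state$iteration, new_compounds = nrow(accepted),
      new_reactions = nrow(new_rx)))
    if (nrow(accepted) == 0 && nrow(new_rx) == 0) break
  }
  state$name_model <- name_model
  state
}

#' Write / read the manual-review queue
#'
#' The queue is a TSV with the candidate pair, its evidence fields and an
#' initially empty `decision` column; a curator (or test harness) fills in
#' `accept`/`reject` and feeds the file back through
#' `review_decisions` of [integrate_databases()].
#'
#' @param state a `gm_match_state` (for writing).
#' @param path TSV file path.
#' @return `read_review_queue` returns the data.frame (with `decision`).
#' @export
write_review_queue <- function(state, path) {
  q <- state$review
  q$decision <- character(nrow(q))
  utils::write.table(q, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_review_queue
#' @export
read_review_queue <- function(path) {
  utils::read.delim(path, colClasses = "character", na.strings = "NA",
                    check.names = FALSE)
}

#' Assign the three confidence tiers
#'
#' The core tier contains every matched compound and every matched reaction,
#' renumbered with local identifiers (seed matches first, then acceptance
#' order).  The intermediate tier adds each unmatched reaction whose full
#' substrate set or full product set (after proton removal) lies in the core
#' compounds, together with the new compounds those reactions introduce; the
#' same chemical entity reaching the intermediate tier from both sources
#' yields deliberate double entries.  The complete tier adds all remaining
#' reactions and compounds.
#'
#' @param dbA,dbB source databases.
#' @param state a fixpoint `gm_match_state`.
#' @param config a [integration_config()] (supplies the id prefix).
#' @return a list of class `gm_tiers` with reconstructions `core`,
#'   `intermediate`, `complete`, plus `reaction_tier` (named by
#'   `"A:<id>"`/`"B:<id>"`, innermost tier of every source reaction) and
#'   `compound_tier`.
#' @export
assign_tiers <- function(dbA, dbB, state, config = integration_config()) {
  prefix <- config$id_prefix
  cm <- state$cmatch
  seed_first <- order(!cm$evidence %in% c("seed_xref", "exact_synonym"))
  cm <- cm[seed_first, , drop = FALSE]

  name_of <- function(db, id) db$compounds[[id]]$names[1]
  compounds <- data.frame(
    local_id = vapply(seq_len(nrow(cm)), function(i) local_id(paste0(prefix, "C"), i), ""),
    id_A = cm$id_A,
    name_A = vapply(cm$id_A, function(i) name_of(dbA, i), ""),
    id_B = cm$id_B,
    name_B = vapply(cm$id_B, function(i) name_of(dbB, i), ""),
    evidence = cm$evidence,
    name_probability = cm$name_probability,
    structure_tier = cm$structure_tier,
    stringsAsFactors = FALSE
  )
  map_A <- stats::setNames(compounds$local_id, compounds$id_A)
  map_B <- stats::setNames(compounds$local_id, compounds$id_B)

  rm_ <- state$rmatch[order(state$rmatch$id_A), , drop = FALSE]
  side_local <- function(side, map, protons) {
    s <- .drop_protons(side, protons)
    data.frame(id = unname(map[s$id]), coef = s$coef, stringsAsFactors = FALSE)
  }
  core_rx <- .empty_recon_reactions()
  for (i in seq_len(nrow(rm_))) {
    rA <- dbA$reactions[[rm_$id_A[i]]]
    rB <- dbB$reactions[[rm_$id_B[i]]]
    row <- data.frame(local_id = local_id(paste0(prefix, "R"), i),
                      id_A = rm_$id_A[i], id_B = rm_$id_B[i],
                      ec = paste(sort(unique(c(rA$ec, rB$ec))), collapse = ";"),
                      stringsAsFactors = FALSE)
    row$substrates <- list(side_local(rA$substrates, map_A, state$protons_A))
    row$products <- list(side_local(rA$products, map_A, state$protons_A))
    core_rx <- rbind(core_rx, row)
  }
  core <- reconstruction("core", compounds, core_rx)

  # -- intermediate and complete tiers ---------------------------------------
  n_cp <- nrow(compounds); n_rx <- nrow(core_rx)
  cp_acc <- compounds        # accumulating compound table
  rx_int <- core_rx
  tier_of_rx <- stats::setNames(
    rep("core", 2 * nrow(rm_)),
    c(paste0("A:", rm_$id_A), paste0("B:", rm_$id_B)))

  unmatched <- list()
  for (id in sort(setdiff(names(dbA$reactions), rm_$id_A))) {
    unmatched[[paste0("A:", id)]] <- list(db = "A", rx = dbA$reactions[[id]])
  }
  for (id in sort(setdiff(names(dbB$reactions), rm_$id_B))) {
    unmatched[[paste0("B:", id)]] <- list(db = "B", rx = dbB$reactions[[id]])
  }

  core_ids_A <- compounds$id_A; core_ids_B <- compounds$id_B
  add_source_compound <- function(db_label, db, sid) {
    # registers a single-source compound, returns its local id
    col <- if (db_label == "A") "id_A" else "id_B"
    hit <- which(cp_acc[[col]] == sid)
    hit <- hit[!is.na(cp_acc[[col]])][1]
    if (!is.na(hit) && length(hit)) return(cp_acc$local_id[hit])
    n_cp <<- n_cp + 1
    lid <- local_id(paste0(prefix, "C"), n_cp)
    row <- data.frame(local_id = lid,
                      id_A = NA_character_, name_A = NA_character_,
                      id_B = NA_character_, name_B = NA_character_,
                      evidence = NA_character_, name_probability = NA_real_,
                      structure_tier = NA_character_, stringsAsFactors = FALSE)
    row[[col]] <- sid
    row[[if (db_label == "A") "name_A" else "name_B"]] <- name_of(db, sid)
    cp_acc <<- rbind(cp_acc, row)
    lid
  }
  make_rx_row <- function(key, entry, db, map_core, protons) {
    rx <- entry$rx
    n_rx <<- n_rx + 1
    s <- .drop_protons(rx$substrates, protons)
    p <- .drop_protons(rx$products, protons)
    loc <- function(side) {
      data.frame(id = vapply(side$id, function(sid) {
        if (!is.na(map_core[sid])) unname(map_core[sid]) else
          add_source_compound(entry$db, db, sid)
      }, ""), coef = side$coef, stringsAsFactors = FALSE)
    }
    row <- data.frame(local_id = local_id(paste0(prefix, "R"), n_rx),
                      id_A = if (entry$db == "A") rx$source_id else NA_character_,
                      id_B = if (entry$db == "B") rx$source_id else NA_character_,
                      ec = paste(sort(unique(rx$ec)), collapse = ";"),
                      stringsAsFactors = FALSE)
    row$substrates <- list(loc(s))
    row$products <- list(loc(p))
    row
  }
  # intermediate pass: full substrate or full product side in core
  inter_keys <- character()
  for (key in names(unmatched)) {
    entry <- unmatched[[key]]
    db <- if (entry$db == "A") dbA else dbB
    protons <- if (entry$db == "A") state$protons_A else state$protons_B
    core_ids <- if (entry$db == "A") core_ids_A else core_ids_B
    s <- .drop_protons(entry$rx$substrates, protons)
    p <- .drop_protons(entry$rx$products, protons)
    if ((nrow(s) && all(s$id %in% core_ids)) ||
        (nrow(p) && all(p$id %in% core_ids))) {
      map_core <- if (entry$db == "A") map_A else map_B
      rx_int <- rbind(rx_int, make_rx_row(key, entry, db, map_core, protons))
      tier_of_rx[key] <- "intermediate"
      inter_keys <- c(inter_keys, key)
    }
  }
  inter_cp <- cp_acc
  intermediate <- reconstruction("intermediate", inter_cp, rx_int)

  # complete pass: everything else
  rx_all <- rx_int
  for (key in setdiff(names(unmatched), inter_keys)) {
    entry <- unmatched[[key]]
    db <- if (entry$db == "A") dbA else dbB
    protons <- if (entry$db == "A") state$protons_A else state$protons_B
    map_core <- if (entry$db == "A") map_A else map_B
    rx_all <- rbind(rx_all, make_rx_row(key, entry, db, map_core, protons))
    tier_of_rx[key] <- "complete"
  }
  # leftover compounds referenced by no reaction at all
  for (sid in sort(setdiff(names(dbA$compounds),
                           c(cp_acc$id_A[!is.na(cp_acc$id_A)], state$protons_A)))) {
    add_source_compound("A", dbA, sid)
  }
  for (sid in sort(setdiff(names(dbB$compounds),
                           c(cp_acc$id_B[!is.na(cp_acc$id_B)], state$protons_B)))) {
    add_source_compound("B", dbB, sid)
  }
  complete <- reconstruction("complete", cp_acc, rx_all)

  compound_tier <- stats::setNames(
    ifelse(cp_acc$local_id %in% core$compounds$local_id, "core",
           ifelse(cp_acc$local_id %in% inter_cp$local_id, "intermediate",
                  "complete")),
    cp_acc$local_id)
  structure(list(core = core, intermediate = intermediate,
                 complete = complete, reaction_tier = tier_of_rx,
                 compound_tier = compound_tier),
            class = "gm_tiers")
}

#' @export
print.gm_tiers <- function(x, ...) {
  for (t in c("core", "intermediate", "complete")) {
    cat(sprintf("%-13s %4d compounds  %4d reactions\n", t,
                nrow(x[[t]]$compounds), nrow(x[[t]]$reactions)))
  }
  invisible(x)
}

#' Pathway coverage of the three tiers
#'
#' Given a pathway-to-EC mapping, tabulates for each pathway how many of its
#' enzymes (EC numbers found in either source database) are attributed to
#' the core and intermediate reconstructions, with percentages relative to
#' the pathway's enzymes present in the complete network.  Pathways with no
#' EC in either database are omitted.
#'
#' @param tiers a `gm_tiers`.
#' @param pathway_map data.frame with columns `pathway`, `ec` (one row per
#'   pathway-EC association), or path to such a TSV.
#' @return data.frame with columns `pathway`, `n_total`, `n_core`,
#'   `pct_core`, `n_intermediate`, `pct_intermediate`, `n_complete`.
#' @export
pathway_coverage <- function(tiers, pathway_map) {
  if (is.character(pathway_map)) {
    pathway_map <- utils::read.delim(pathway_map, colClasses = "character",
                                     check.names = FALSE)
  }
  if (!nrow(pathway_map)) {
    return(data.frame(pathway = character(), n_total = integer(),
                      n_core = integer(), pct_core = numeric(),
                      n_intermediate = integer(), pct_intermediate = numeric(),
                      n_complete = integer(), stringsAsFactors = FALSE))
  }
  tier_ecs <- function(recon) {
    unique(unlist(strsplit(recon$reactions$ec, ";", fixed = TRUE)))
  }
  ec_core <- tier_ecs(tiers$core)
  ec_int <- tier_ecs(tiers$intermediate)
  ec_all <- tier_ecs(tiers$complete)
  out <- do.call(rbind, lapply(split(pathway_map$ec, pathway_map$pathway),
                               function(ecs) {
    ecs <- unique(ecs)
    present <- intersect(ecs, ec_all)
    if (!length(present)) return(NULL)
    data.frame(n_total = length(present),
               n_core = length(intersect(ecs, ec_core)),
               n_intermediate = length(intersect(ecs, ec_int)),
               n_complete = length(present), stringsAsFactors = FALSE)
  }))
  out$pathway <- rownames(out)
  rownames(out) <- NULL
  out$pct_core <- 100 * out$n_core / out$n_total
  out$pct_intermediate <- 100 * out$n_intermediate / out$n_total
  out[, c("pathway", "n_total", "n_core", "pct_core",
          "n_intermediate", "pct_intermediate", "n_complete")]
}
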