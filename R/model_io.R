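# Domain types and flat-file I/O for the two-database integration pipeline.
#
# Source dialect (one directory per database):
#   compounds.tsv: id | names (pipe-sep, first = preferred) | formula (Hill) |
#                  smiles | xrefs (semicolon-sep "NS:id") | is_generic (0/1)
#   reactions.tsv: id | stoichiometry ("1 C1 + 2 C2 = 1 C3") | ec (semicolon) |
#                  reversible (0/1) | pathways (pipe-sep)
#
# Reconstruction dialect: two TSVs per tier (compounds.tsv, reactions.tsv)
# with local identifiers "Ath_C%04d"/"Ath_R%04d", stoichiometry strings over
# local compound ids with explicit unit coefficients.

#' Construct a compound record
#'
#' @param source_db `"A"` or `"B"`.
#' @param source_id non-empty identifier, unique within its database.
#' @param names character vector of synonyms; the first is the preferred name.
#' @param formula named integer vector of element counts, or `NULL`.
#' @param smiles SMILES string or `NA`.
#' @param xrefs character vector of `"NAMESPACE:id"` cross-references.
#' @param is_generic `TRUE` for generic compound classes (e.g. "an alcohol"),
#'   which carry no structure.
#' @return a list of class `gm_compound`.
#' @export
compound_record <- function(source_db, source_id, names, formula = NULL,
                            smiles = NA_character_, xrefs = character(),
                            is_generic = FALSE) {
  if (!source_db %in% c("A", "B")) stop_gm("source_db must be 'A' or 'B'")
  if (!nzchar(source_id)) stop_gm("source_id must be non-empty")
  if (!length(names) || !all(nzchar(names))) {
    stop_gm("compound ", source_id, ": names must be non-empty")
  }
  if (!is.null(formula) && any(formula < 0)) {
    stop_gm("compound ", source_id, ": negative formula counts")
  }
  if (is_generic && !is.na(smiles) && nzchar(smiles)) {
    stop_gm("compound ", source_id, ": generic classes cannot carry a structure")
  }
  structure(list(source_db = source_db, source_id = source_id,
                 names = as.character(names), formula = formula,
                 smiles = if (is.na(smiles) || !nzchar(smiles)) NA_character_ else smiles,
                 xrefs = as.character(xrefs), is_generic = isTRUE(is_generic)),
            class = "gm_compound")
}

#' Construct a reaction record
#'
#' @param source_db `"A"` or `"B"`.
#' @param source_id non-empty identifier, unique within its database.
#' @param substrates,products data.frames with columns `id` (compound
#'   source id) and `coef` (positive coefficient).
#' @param ec character vector of EC numbers (possibly partial, e.g.
#'   `"2.7.1.-"`).
#' @param reversible logical; reaction directionality is generally ambiguous,
#'   so the default is `TRUE`.
#' @param pathways character vector of pathway tags.
#' @return a list of class `gm_reaction`.
#' @export
reaction_record <- function(source_db, source_id, substrates, products,
                            ec = character(), reversible = TRUE,
                            pathways = character()) {
  if (!source_db %in% c("A", "B")) stop_gm("source_db must be 'A' or 'B'")
  if (!nzchar(source_id)) stop_gm("source_id must be non-empty")
  side_ok <- function(s, lab) {
    if (!is.data.frame(s) || !all(c("id", "coef") %in% names(s)) || !nrow(s)) {
      stop_gm("reaction ", source_id, ": ", lab, " side must be a non-empty ",
              "data.frame with columns id, coef")
    }
    if (any(s$coef <= 0)) {
      stop_gm("reaction ", source_id, ": coefficients must be positive")
    }
    s[, c("id", "coef")]
  }
  structure(list(source_db = source_db, source_id = source_id,
                 substrates = side_ok(substrates, "substrate"),
                 products = side_ok(products, "product"),
                 ec = as.character(ec), reversible = isTRUE(reversible),
                 pathways = as.character(pathways)),
            class = "gm_reaction")
}

#' Bundle compound and reaction records into a source database
#'
#' Checks referential integrity (every compound id used by a reaction must
#' resolve) and source-id uniqueness.
#'
#' @param compounds list of [compound_record()]s.
#' @param reactions list of [reaction_record()]s.
#' @param label `"A"` or `"B"`.
#' @return a list of class `gm_source_db` with named `compounds` and
#'   `reactions` lists.
#' @export
source_db <- function(compounds, reactions, label) {
  cid <- vapply(compounds, `[[`, "", "source_id")
  if (anyDuplicated(cid)) {
    stop_gm("duplicate compound source_id: ",
            paste(unique(cid[duplicated(cid)]), collapse = ", "))
  }
  rid <- vapply(reactions, `[[`, "", "source_id")
  if (anyDuplicated(rid)) {
    stop_gm("duplicate reaction source_id: ",
            paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  names(compounds) <- cid
  names(reactions) <- rid
  dangling <- unique(unlist(lapply(reactions, function(r) {
    setdiff(c(r$substrates$id, r$products$id), cid)
  })))
  if (length(dangling)) {
    stop_gm("reactions reference unknown compound id(s): ",
            paste(dangling, collapse = ", "))
  }
  structure(list(label = label, compounds = compounds, reactions = reactions),
            class = "gm_source_db")
}

#' @export
print.gm_source_db <- function(x, ...) {
  cat(sprintf("<source database %s: %d compounds, %d reactions>\n",
              x$label, length(x$compounds), length(x$reactions)))
  invisible(x)
}

.split_field <- function(x, sep) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, sep, fixed = TRUE)[[1]]
}

#' Read a source database from its flat-file dialect
#'
#' @param path directory containing `compounds.tsv` and `reactions.tsv`.
#' @param db_label `"A"` or `"B"`.
#' @return a [source_db()] object.
#' @export
read_source_db <- function(path, db_label) {
  cf <- file.path(path, "compounds.tsv")
  rf <- file.path(path, "reactions.tsv")
  if (!file.exists(cf) || !file.exists(rf)) {
    stop_gm("expected compounds.tsv and reactions.tsv under ", path)
  }
  ct <- utils::read.delim(cf, colClasses = "character", na.strings = NULL,
                          check.names = FALSE, comment.char = "#")
  compounds <- lapply(seq_len(nrow(ct)), function(i) {
    row <- ct[i, ]
    compound_record(
      source_db = db_label,
      source_id = row$id,
      names = .split_field(row$names, "|"),
      formula = parse_formula(row$formula),
      smiles = if (nzchar(row$smiles)) row$smiles else NA_character_,
      xrefs = .split_field(row$xrefs, ";"),
      is_generic = row$is_generic == "1"
    )
  })
  rt <- utils::read.delim(rf, colClasses = "character", na.strings = NULL,
                          check.names = FALSE, comment.char = "#")
  reactions <- lapply(seq_len(nrow(rt)), function(i) {
    row <- rt[i, ]
    sides <- tryCatch(parse_stoichiometry(row$stoichiometry),
                      error = function(e) {
                        stop_gm("reactions.tsv line ", i + 1, " (", row$id,
                                "): ", conditionMessage(e))
                      })
    reaction_record(
      source_db = db_label,
      source_id = row$id,
      substrates = sides$substrates,
      products = sides$products,
      ec = .split_field(row$ec, ";"),
      reversible = row$reversible != "0",
      pathways = .split_field(row$pathways, "|")
    )
  })
  source_db(compounds, reactions, db_label)
}

#' Write a source database in the flat-file dialect
#'
#' Inverse of [read_source_db()]; the round trip is loss-free.
#'
#' @param db a [source_db()] object.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_source_db <- function(db, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ct <- data.frame(
    id = vapply(db$compounds, `[[`, "", "source_id"),
    names = vapply(db$compounds, function(c) paste(c$names, collapse = "|"), ""),
    formula = vapply(db$compounds, function(c) format_formula(c$formula), ""),
    smiles = vapply(db$compounds, function(c) ifelse(is.na(c$smiles), "", c$smiles), ""),
    xrefs = vapply(db$compounds, function(c) paste(c$xrefs, collapse = ";"), ""),
    is_generic = vapply(db$compounds, function(c) ifelse(c$is_generic, "1", "0"), ""),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.table(ct, file.path(path, "compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rt <- data.frame(
    id = vapply(db$reactions, `[[`, "", "source_id"),
    stoichiometry = vapply(db$reactions, function(r) {
      format_stoichiometry(r$substrates, r$products)
    }, ""),
    ec = vapply(db$reactions, function(r) paste(r$ec, collapse = ";"), ""),
    reversible = vapply(db$reactions, function(r) ifelse(r$reversible, "1", "0"), ""),
    pathways = vapply(db$reactions, function(r) paste(r$pathways, collapse = "|"), ""),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.table(rt, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a stoichiometry string
#'
#' The dialect separates substrates from products with a single `=` sign,
#' terms with `+`, and mandates an explicit coefficient even when it is one:
#' `"1 Ath_C0001 + 1 Ath_C0002 = 1 Ath_C0003"`.  Coefficients may be integers,
#' fractions (`"1/2"`) or decimals; they are parsed exactly.
#'
#' @param s a stoichiometry string.
#' @return list with data.frames `substrates` and `products` (columns `id`,
#'   `coef`).
#' @export
parse_stoichiometry <- function(s) {
  halves <- strsplit(s, "=", fixed = TRUE)[[1]]
  if (length(halves) != 2 || !nzchar(trimws(halves[1])) || !nzchar(trimws(halves[2]))) {
    stop_gm("stoichiometry must contain exactly one '=' with both sides ",
            "non-empty: ", s)
  }
  side <- function(h) {
    terms <- trimws(strsplit(h, "+", fixed = TRUE)[[1]])
    ids <- character(length(terms))
    coefs <- numeric(length(terms))
    for (i in seq_along(terms)) {
      tok <- strsplit(terms[i], "[ \t]+")[[1]]
      tok <- tok[nzchar(tok)]
      if (length(tok) != 2) {
        stop_gm("each term must be '<coefficient> <compound id>' ",
                "(the coefficient is explicit even when it is 1): '",
                terms[i], "'")
      }
      cf <- if (grepl("^[0-9]+/[0-9]+$", tok[1])) {
        p <- as.numeric(strsplit(tok[1], "/", fixed = TRUE)[[1]])
        p[1] / p[2]
      } else {
        suppressWarnings(as.numeric(tok[1]))
      }
      if (is.na(cf) || cf <= 0) stop_gm("invalid coefficient '", tok[1], "'")
      ids[i] <- tok[2]
      coefs[i] <- cf
    }
    data.frame(id = ids, coef = coefs, stringsAsFactors = FALSE)
  }
  list(substrates = side(halves[1]), products = side(halves[2]))
}

#' Format reaction sides as a stoichiometry string
#'
#' Inverse of [parse_stoichiometry()].  Unit coefficients are written
#' explicitly; fractional coefficients are written as reduced fractions.
#'
#' @param substrates,products data.frames with columns `id`, `coef`.
#' @return a stoichiometry string.
#' @export
format_stoichiometry <- function(substrates, products) {
  fmt_coef <- function(x) {
    r <- rationalize(x)
    ifelse(r$den == 1, format(r$num, scientific = FALSE),
           paste0(r$num, "/", r$den))
  }
  side <- function(s) {
    paste(paste(fmt_coef(s$coef), s$id), collapse = " + ")
  }
  paste(side(substrates), "=", side(products))
}

# -- reconstructions ----------------------------------------------------------

#' Construct a tiered reconstruction
#'
#' @param tier `"core"`, `"intermediate"` or `"complete"`.
#' @param compounds data.frame with columns `local_id`, `id_A`, `name_A`,
#'   `id_B`, `name_B`, `evidence`, `name_probability`, `structure_tier`.
#' @param reactions data.frame with columns `local_id`, `id_A`, `id_B`, `ec`
#'   plus list-columns `substrates`, `products` of data.frames
#'   (`id` = local compound id, `coef`).
#' @return a list of class `gm_reconstruction`.
#' @export
reconstruction <- function(tier, compounds, reactions) {
  tier <- match.arg(tier, c("core", "intermediate", "complete"))
  stopifnot(is.data.frame(compounds), is.data.frame(reactions))
  if (anyDuplicated(compounds$local_id)) stop_gm("duplicate compound local_id")
  if (anyDuplicated(reactions$local_id)) stop_gm("duplicate reaction local_id")
  known <- compounds$local_id
  for (i in seq_len(nrow(reactions))) {
    ids <- c(reactions$substrates[[i]]$id, reactions$products[[i]]$id)
    bad <- setdiff(ids, known)
    if (length(bad)) {
      stop_gm("reaction ", reactions$local_id[i],
              " references unknown compound(s): ", paste(bad, collapse = ", "))
    }
  }
  if (tier == "core" &&
      nrow(compounds) && (anyNA(compounds$id_A) || anyNA(compounds$id_B))) {
    stop_gm("core-tier compounds must be matched in both databases")
  }
  structure(list(tier = tier, compounds = compounds, reactions = reactions),
            class = "gm_reconstruction")
}

#' @export
print.gm_reconstruction <- function(x, ...) {
  cat(sprintf("<%s reconstruction: %d compounds, %d reactions>\n",
              x$tier, nrow(x$compounds), nrow(x$reactions)))
  invisible(x)
}

.empty_recon_compounds <- function() {
  data.frame(local_id = character(), id_A = character(), name_A = character(),
             id_B = character(), name_B = character(), evidence = character(),
             name_probability = numeric(), structure_tier = character(),
             stringsAsFactors = FALSE)
}

.empty_recon_reactions <- function() {
  out <- data.frame(local_id = character(), id_A = character(),
                    id_B = character(), ec = character(),
                    stringsAsFactors = FALSE)
  out$substrates <- list()
  out$products <- list()
  out
}

#' Write a reconstruction as two TSV files
#'
#' `compounds.tsv` lists local id, both source ids and names, and match
#' evidence; `reactions.tsv` lists local id, source ids, the stoichiometry
#' string over local compound ids (explicit unit coefficients, `=` separator)
#' and the EC list.  Rows are sorted by local id so output is deterministic.
#'
#' @param recon a [reconstruction()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(recon, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cp <- recon$compounds[order(recon$compounds$local_id), , drop = FALSE]
  na2e <- function(x) ifelse(is.na(x), "", x)
  ct <- data.frame(
    local_id = cp$local_id, id_A = na2e(cp$id_A), name_A = na2e(cp$name_A),
    id_B = na2e(cp$id_B), name_B = na2e(cp$name_B),
    evidence = na2e(cp$evidence),
    name_probability = ifelse(is.na(cp$name_probability), "",
                              format(cp$name_probability, digits = 15)),
    structure_tier = na2e(cp$structure_tier),
    stringsAsFactors = FALSE
  )
  utils::write.table(ct, file.path(path, "compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rc <- recon$reactions
  ord <- order(rc$local_id)
  rt <- data.frame(
    local_id = rc$local_id[ord], id_A = na2e(rc$id_A[ord]),
    id_B = na2e(rc$id_B[ord]),
    stoichiometry = vapply(ord, function(i) {
      format_stoichiometry(rc$substrates[[i]], rc$products[[i]])
    }, ""),
    ec = na2e(rc$ec[ord]),
    stringsAsFactors = FALSE
  )
  utils::write.table(rt, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reconstruction written by [write_reconstruction()]
#'
#' @param path directory holding `compounds.tsv` and `reactions.tsv`.
#' @param tier tier label to attach.
#' @return a [reconstruction()].
#' @export
read_reconstruction <- function(path, tier = "core") {
  ct <- utils::read.delim(file.path(path, "compounds.tsv"),
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  e2na <- function(x) ifelse(nzchar(x), x, NA_character_)
  compounds <- data.frame(
    local_id = ct$local_id, id_A = e2na(ct$id_A), name_A = e2na(ct$name_A),
    id_B = e2na(ct$id_B), name_B = e2na(ct$name_B),
    evidence = e2na(ct$evidence),
    name_probability = suppressWarnings(as.numeric(ct$name_probability)),
    structure_tier = e2na(ct$structure_tier),
    stringsAsFactors = FALSE
  )
  rt <- utils::read.delim(file.path(path, "reactions.tsv"),
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  sides <- lapply(rt$stoichiometry, parse_stoichiometry)
  reactions <- data.frame(
    local_id = rt$local_id, id_A = e2na(rt$id_A), id_B = e2na(rt$id_B),
    ec = rt$ec, stringsAsFactors = FALSE
  )
  reactions$substrates <- lapply(sides, `[[`, "substrates")
  reactions$products <- lapply(sides, `[[`, "products")
  reconstruction(tier, compounds, reactions)
}
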