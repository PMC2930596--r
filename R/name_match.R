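# Logistic-regression string-similarity scorer for metabolite names.
#
# Chemical synonyms differ in systematic ways ("-ic acid" vs "-ate", Greek
# letter spellings, locant punctuation, acronyms), so a generic edit distance
# is a poor classifier.  Instead, symmetric features of a name pair feed a
# ridge-penalized logistic regression trained on within-database synonym sets
# (names known to denote the same compound) against formula-discordant
# negative pairs (names guaranteed to denote different compounds).

.greek_map <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "ω" = "omega"
)

#' Normalize a metabolite name for comparison
#'
#' Lowercases, spells out Greek letters, collapses whitespace/hyphen runs to
#' single separators and strips punctuation other than chemical locant
#' separators (hyphens, commas, apostrophes between alphanumerics are kept as
#' token structure; everything is reduced to lowercase alphanumeric tokens
#' separated by single hyphens/spaces).
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  y <- tolower(trimws(x))
  for (g in names(.greek_map)) y <- gsub(g, .greek_map[[g]], y, fixed = TRUE)
  y <- gsub("[_’']", "", y)
  y <- gsub("[](){}\"[]", "", y)
  y <- gsub("[,;:]+", "-", y)
  y <- gsub("[ \t]+", " ", y)
  y <- gsub("-+", "-", y)
  y <- gsub(" ?- ?", "-", y)
  trimws(y)
}

.tokens <- function(x) {
  t <- strsplit(x, "[^a-z0-9]+")[[1]]
  t[nzchar(t)]
}

.bigrams <- function(x) {
  x <- gsub("[^a-z0-9]", "", x)
  n <- nchar(x)
  if (n < 2) return(x)
  substring(x, 1:(n - 1), 2:n)
}

.multiset_intersection_size <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  sum(pmin(ta[common], tb[common]))
}

.digit_tokens <- function(x) {
  m <- gregexpr("[0-9]+", x)[[1]]
  if (m[1] == -1) character() else regmatches(x, list(m))[[1]]
}

.acronym_of <- function(tok) paste(substring(tok, 1, 1), collapse = "")

# canonical form under the acid/conjugate-base naming interchange:
# "...ic acid" and "...ate" denote the same species in metabolic usage
.suffix_canon <- function(x) {
  x <- sub("ic acid$", "ate", x)
  sub("ic-acid$", "ate", x)
}

#' Extract symmetric similarity features for a name pair
#'
#' Features: character-bigram Dice coefficient; longest common prefix and
#' suffix lengths normalized by the shorter name; agreement of the digit-token
#' multisets (locants, chain lengths); acronym compatibility (a short
#' single-token name may abbreviate the initials of the other's tokens);
#' counts of common and differing lowercase alphanumeric tokens; substring
#' containment; equality, bigram Dice and edit similarity after
#' canonicalizing the acid/conjugate-base suffix ("-ic acid" vs "-ate");
#' and raw edit similarity.  All features are invariant to swapping the
#' pair.
#'
#' @param a,b names (normalized internally via [normalize_name()]).
#' @return named numeric vector of features.
#' @export
name_features <- function(a, b) {
  a <- normalize_name(a); b <- normalize_name(b)
  if (!nzchar(a) || !nzchar(b)) stop_gm("cannot featurize an empty name")
  ga <- .bigrams(a); gb <- .bigrams(b)
  dice <- if (!length(ga) && !length(gb)) 1 else {
    2 * .multiset_intersection_size(ga, gb) / (length(ga) + length(gb))
  }
  ca <- strsplit(gsub("[^a-z0-9]", "", a), "")[[1]]
  cb <- strsplit(gsub("[^a-z0-9]", "", b), "")[[1]]
  shorter <- max(1, min(length(ca), length(cb)))
  npre <- 0
  while (npre < min(length(ca), length(cb)) && ca[npre + 1] == cb[npre + 1]) {
    npre <- npre + 1
  }
  nsuf <- 0
  while (nsuf < min(length(ca), length(cb)) &&
         ca[length(ca) - nsuf] == cb[length(cb) - nsuf]) {
    nsuf <- nsuf + 1
  }
  da <- .digit_tokens(a); db <- .digit_tokens(b)
  digits_agree <- length(da) == length(db) &&
    all(sort(da) == sort(db))
  ta <- .tokens(a); tb <- .tokens(b)
  acro <- TRUE
  if (length(ta) == 1 && nchar(ta) <= 5 && length(tb) >= 2 &&
      !grepl("[0-9]", ta)) {
    acro <- identical(ta, .acronym_of(tb))
  } else if (length(tb) == 1 && nchar(tb) <= 5 && length(ta) >= 2 &&
             !grepl("[0-9]", tb)) {
    acro <- identical(tb, .acronym_of(ta))
  }
  common <- .multiset_intersection_size(ta, tb)
  different <- (length(ta) - common) + (length(tb) - common)
  ca_str <- paste(ca, collapse = ""); cb_str <- paste(cb, collapse = "")
  containment <- grepl(ca_str, cb_str, fixed = TRUE) ||
    grepl(cb_str, ca_str, fixed = TRUE)
  canon_a <- .suffix_canon(a); canon_b <- .suffix_canon(b)
  suffix_interchange <- identical(canon_a, canon_b)
  canon_ga <- .bigrams(canon_a); canon_gb <- .bigrams(canon_b)
  canon_dice <- if (!length(canon_ga) && !length(canon_gb)) 1 else {
    2 * .multiset_intersection_size(canon_ga, canon_gb) /
      (length(canon_ga) + length(canon_gb))
  }
  lev_sim <- function(x, y) {
    1 - as.numeric(utils::adist(x, y)) / max(nchar(x), nchar(y))
  }
  c(bigram_dice = dice,
    prefix_match = npre / shorter,
    suffix_match = nsuf / shorter,
    number_tokens_agree = as.numeric(digits_agree),
    acronym_compatible = as.numeric(acro),
    common_token_count = common,
    different_token_count = different,
    containment = as.numeric(containment),
    suffix_interchange = as.numeric(suffix_interchange),
    canon_dice = canon_dice,
    edit_similarity = lev_sim(a, b),
    canon_edit_similarity = lev_sim(canon_a, canon_b))
}

.feature_names <- c("bigram_dice", "prefix_match", "suffix_match",
                    "number_tokens_agree", "acronym_compatible",
                    "common_token_count", "different_token_count",
                    "containment", "suffix_interchange", "canon_dice",
                    "edit_similarity", "canon_edit_similarity")

.feature_matrix <- function(a, b) {
  t(mapply(name_features, a, b, USE.NAMES = FALSE))
}

#' Build a labeled training set of name pairs from one or more databases
#'
#' Positive pairs are all unordered pairs of synonyms listed for the same
#' compound.  Negative pairs are sampled from names of distinct compounds
#' whose formulas differ in at least one non-hydrogen element, which
#' guarantees the two names cannot denote the same molecule.
#'
#' Synonym sets also contain lexically unrelated aliases (formula
#' abbreviations such as "H2O", trivial versus systematic names); such pairs
#' carry no signal a string model could learn and are resolved upstream by
#' the exact-synonym and cross-reference channels, so positive pairs below
#' `min_lexical_overlap` bigram Dice are excluded from training.
#'
#' @param db a `gm_source_db`, or a list of them to pool.
#' @param negatives_per_positive how many negatives to sample per positive
#'   pair (default 1, i.e. class-balanced).
#' @param seed integer seed controlling negative sampling.
#' @param min_lexical_overlap minimum bigram Dice for a positive pair to
#'   enter the training set (default 0.2).
#' @return data.frame with columns `name_a`, `name_b`, `label` (1/0).
#' @export
build_training_set <- function(db, negatives_per_positive = 1, seed = 1,
                               min_lexical_overlap = 0.3) {
  dbs <- if (inherits(db, "gm_source_db")) list(db) else db
  compounds <- unlist(lapply(dbs, `[[`, "compounds"), recursive = FALSE)
  pos_a <- character(); pos_b <- character()
  for (cp in compounds) {
    nm <- unique(cp$names)
    if (length(nm) >= 2) {
      idx <- utils::combn(length(nm), 2)
      for (k in seq_len(ncol(idx))) {
        a <- nm[idx[1, k]]; b <- nm[idx[2, k]]
        if (name_features(a, b)[["bigram_dice"]] >= min_lexical_overlap) {
          pos_a <- c(pos_a, a)
          pos_b <- c(pos_b, b)
        }
      }
    }
  }
  if (!length(pos_a)) stop_gm("insufficient training data: no compound has ",
                              "two or more synonyms")
  formulas <- lapply(compounds, `[[`, "formula")
  has_f <- which(!vapply(formulas, is.null, TRUE))
  n_neg <- round(length(pos_a) * negatives_per_positive)
  neg_a <- character(0); neg_b <- character(0)
  with_seed(seed, {
    guard <- 0
    while (length(neg_a) < n_neg && guard < 50 * n_neg + 100) {
      guard <- guard + 1
      ij <- sample(has_f, 2)
      if (formula_equal_ignoring_h(formulas[[ij[1]]], formulas[[ij[2]]])) next
      na <- sample(compounds[[ij[1]]]$names, 1)
      nb <- sample(compounds[[ij[2]]]$names, 1)
      neg_a <- c(neg_a, na); neg_b <- c(neg_b, nb)
    }
  })
  data.frame(name_a = c(pos_a, neg_a), name_b = c(pos_b, neg_b),
             label = c(rep(1L, length(pos_a)), rep(0L, length(neg_a))),
             stringsAsFactors = FALSE)
}

#' Train the name-similarity model
#'
#' Fits an L2-regularized (ridge) logistic regression on the pair features.
#' The returned score is a probability that two names denote the same
#' compound; it is exactly symmetric in its arguments because every feature
#' is.
#'
#' @param pairs data.frame from [build_training_set()].
#' @param l2 regularization strength (glmnet lambda is `l2 / n`).
#' @param threshold acceptance threshold stored with the model (pairs scoring
#'   in `[0.5, threshold)` are routed to manual review downstream).
#' @return a list of class `gm_name_model` with `weights`, `bias`,
#'   `threshold`.
#' @export
train_name_model <- function(pairs, l2 = 1, threshold = 0.9) {
  if (length(unique(pairs$label)) < 2) {
    stop_gm("degenerate training set: both classes are required")
  }
  x <- .feature_matrix(pairs$name_a, pairs$name_b)
  colnames(x) <- .feature_names
  fit <- glmnet::glmnet(x, pairs$label, family = "binomial", alpha = 0,
                        lambda = l2 / nrow(x), standardize = FALSE)
  cf <- as.numeric(stats::coef(fit, s = l2 / nrow(x)))
  model <- list(weights = stats::setNames(cf[-1], .feature_names),
                bias = cf[1], threshold = threshold)
  class(model) <- "gm_name_model"
  model
}

#' Score the similarity of two names
#'
#' @param model a `gm_name_model`.
#' @param a,b character vectors of names (recycled to a common length).
#' @return probabilities in `(0, 1)` that each pair denotes one compound.
#' @export
score_names <- function(model, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  x <- .feature_matrix(a, b)
  as.numeric(stats::plogis(model$bias + x %*% model$weights))
}

#' @export
print.gm_name_model <- function(x, ...) {
  cat("<name-similarity model>\n  bias:", format(x$bias, digits = 4), "\n")
  for (f in names(x$weights)) {
    cat(sprintf("  %-24s % .4f\n", f, x$weights[[f]]))
  }
  invisible(x)
}

#' Serialize / restore a name model as JSON
#'
#' @param model a `gm_name_model`.
#' @param path JSON file path.
#' @return `read_name_model` returns the model; `write_name_model` the path,
#'   invisibly.
#' @export
write_name_model <- function(model, path) {
  jsonlite::write_json(list(features = names(model$weights),
                            weights = unname(model$weights),
                            bias = model$bias, threshold = model$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_name_model
#' @export
read_name_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(weights = stats::setNames(as.numeric(j$weights), j$features),
                bias = as.numeric(j$bias), threshold = as.numeric(j$threshold))
  class(model) <- "gm_name_model"
  model
}
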