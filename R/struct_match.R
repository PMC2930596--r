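# Chemical-structure comparison ladder.
#
# All molecule-level normalization is delegated to OpenBabel (`obabel` on the
# PATH), invoked once per batch:
#   canonical           "can" output format
#   stereo purge        stereo descriptors stripped, then re-canonicalized
#   tautomer normal     standard InChI (its mobile-H layer merges common
#                       tautomers); compared with stereo layers dropped
#   pH 7.4 reionized    obabel -p 7.4 protonation model, canonical SMILES
#   fingerprint         ECFP4 circular fingerprint (hex output, parsed to
#                       bit positions)

.obabel_available <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- nzchar(Sys.which("obabel"))
    cache
  }
})

# Run obabel over a batch of SMILES, one output line per input.  Inputs are
# tagged with index titles so failures can be mapped back; a failed molecule
# yields NA.
.ob_batch <- function(smiles, args) {
  if (!length(smiles)) return(character())
  if (!.obabel_available()) stop_gm("obabel not found on PATH")
  inf <- tempfile(fileext = ".smi")
  outf <- tempfile(fileext = ".txt")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  writeLines(paste(smiles, sprintf("m%06d", seq_along(smiles))), inf)
  res <- suppressWarnings(system2("obabel", c(inf, args, "-O", outf),
                                  stdout = TRUE, stderr = TRUE))
  out <- rep(NA_character_, length(smiles))
  if (!file.exists(outf)) return(out)
  lines <- readLines(outf, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    tag <- parts[length(parts)]
    if (grepl("^m[0-9]{6}$", tag)) {
      i <- as.integer(sub("^m", "", tag))
      out[i] <- paste(parts[-length(parts)], collapse = " ")
    }
  }
  out
}

.ob_canonical <- function(smiles) .ob_batch(smiles, c("-ocan"))
.ob_ph74 <- function(smiles) .ob_batch(smiles, c("-ocan", "-p", "7.4"))

# InChI output carries no molecule title, so alignment relies on obabel
# emitting one line per successfully converted molecule; if any molecule in
# the batch fails, fall back to per-molecule conversion.
.ob_inchi <- function(smiles) {
  if (!length(smiles)) return(character())
  if (!.obabel_available()) stop_gm("obabel not found on PATH")
  inf <- tempfile(fileext = ".smi")
  outf <- tempfile(fileext = ".inchi")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  writeLines(smiles, inf)
  suppressWarnings(system2("obabel", c(inf, "-oinchi", "-O", outf),
                           stdout = FALSE, stderr = FALSE))
  lines <- if (file.exists(outf)) readLines(outf, warn = FALSE) else character()
  lines <- lines[grepl("^InChI=", lines)]
  if (length(lines) == length(smiles)) return(lines)
  vapply(smiles, function(s) {
    f1 <- tempfile(fileext = ".smi"); f2 <- tempfile(fileext = ".inchi")
    on.exit(unlink(c(f1, f2)), add = TRUE)
    writeLines(s, f1)
    suppressWarnings(system2("obabel", c(f1, "-oinchi", "-O", f2),
                             stdout = FALSE, stderr = FALSE))
    r <- if (file.exists(f2)) readLines(f2, warn = FALSE) else character()
    r <- r[grepl("^InChI=", r)]
    if (length(r)) r[1] else NA_character_
  }, "", USE.NAMES = FALSE)
}

# ECFP4 fingerprints as sorted integer bit positions.  Parses the hex block
# format of obabel's fpt output (32-bit words, least significant word first).
.ob_ecfp4 <- function(smiles) {
  if (!length(smiles)) return(list())
  if (!.obabel_available()) stop_gm("obabel not found on PATH")
  inf <- tempfile(fileext = ".smi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(paste(smiles, sprintf("m%06d", seq_along(smiles))), inf)
  lines <- suppressWarnings(system2(
    "obabel", c(inf, "-ofpt", "-xfECFP4", "-xh"), stdout = TRUE, stderr = FALSE))
  fps <- rep(list(NULL), length(smiles))
  cur <- NA_integer_
  hex <- character()
  flush <- function(cur, hex, fps) {
    if (!is.na(cur) && length(hex)) {
      words <- rev(hex)  # printed most-significant first
      bits <- integer()
      for (w in seq_along(words)) {
        v <- strtoi(substring(words[w], 1:8, 1:8), base = 16L)
        # v: 8 nibbles, most significant first within the word
        for (nb in 1:8) {
          if (v[nb] > 0) {
            for (b in 0:3) {
              if (bitwAnd(v[nb], bitwShiftL(1L, b)) != 0) {
                bits <- c(bits, (w - 1L) * 32L + (8L - nb) * 4L + b)
              }
            }
          }
        }
      }
      fps[[cur]] <- sort(bits)
    }
    fps
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      fps <- flush(cur, hex, fps)
      hex <- character()
      m <- regmatches(ln, regexpr("m[0-9]{6}", ln))
      cur <- if (length(m)) as.integer(sub("^m", "", m)) else NA_integer_
    } else {
      hx <- regmatches(ln, gregexpr("[0-9a-fA-F]{8}", ln))[[1]]
      hex <- c(hex, hx)
    }
  }
  fps <- flush(cur, hex, fps)
  fps
}

.strip_stereo <- function(smiles) {
  s <- gsub("[/\\\\]", "", smiles)
  s <- gsub("@", "", s, fixed = TRUE)
  # collapse brackets that became redundant, e.g. [CH] from [C@H]: leave to
  # canonicalization, which accepts bracketed atoms as-is
  s
}

# Drop stereo (/t /m /s /b) and protonation (/p /q) layers from an InChI.
.inchi_core <- function(inchi, drop_protonation = FALSE) {
  if (is.na(inchi)) return(NA_character_)
  layers <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  drop <- c("t", "m", "s", "b")
  if (drop_protonation) drop <- c(drop, "p", "q")
  keep <- c(TRUE, !substring(layers[-1], 1, 1) %in% drop)
  paste(layers[keep], collapse = "/")
}

#' Compute the normalized structure forms of a batch of molecules
#'
#' For each SMILES string, derives the canonical SMILES, the
#' stereochemistry-purged canonical SMILES, a tautomer-invariant key
#' (standard InChI with stereo layers dropped; the InChI mobile-H convention
#' canonicalizes common tautomers), the canonical SMILES after reionization
#' at pH 7.4, and an ECFP4 circular fingerprint.
#'
#' @param smiles character vector of SMILES strings (`NA` entries allowed and
#'   propagated).
#' @return a list of class `gm_structure_forms` per molecule, each with
#'   fields `canonical`, `stereo_purged`, `tautomer_key`, `ph74`,
#'   `fingerprint` (sorted integer bit positions).  A single input returns
#'   the bare form object.
#' @export
structure_forms <- function(smiles) {
  n <- length(smiles)
  ok <- !is.na(smiles) & nzchar(smiles)
  canonical <- stereo <- taut <- ph <- rep(NA_character_, n)
  fps <- rep(list(NULL), n)
  if (any(ok)) {
    canonical[ok] <- .ob_canonical(smiles[ok])
    bad <- ok & is.na(canonical)
    if (any(bad)) {
      stop_gm("unparseable SMILES: ", paste(smiles[bad], collapse = ", "))
    }
    stereo[ok] <- .ob_canonical(.strip_stereo(canonical[ok]))
    inchi <- .ob_inchi(canonical[ok])
    taut[ok] <- vapply(inchi, .inchi_core, "", USE.NAMES = FALSE)
    ph[ok] <- .ob_ph74(canonical[ok])
    fps[ok] <- .ob_ecfp4(canonical[ok])
  }
  forms <- lapply(seq_len(n), function(i) {
    structure(list(canonical = canonical[i], stereo_purged = stereo[i],
                   tautomer_key = taut[i], ph74 = ph[i],
                   fingerprint = fps[[i]]),
              class = "gm_structure_forms")
  })
  if (n == 1) forms[[1]] else forms
}

#' Tanimoto similarity of two bit-set fingerprints
#'
#' `|a AND b| / |a OR b|` over set bit positions.  Two empty fingerprints
#' return 1 by convention (degenerate case).
#'
#' @param fa,fb integer vectors of set bit positions.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fa, fb) {
  if (is.null(fa) || is.null(fb)) stop_gm("missing fingerprint")
  u <- length(union(fa, fb))
  if (u == 0) return(1)
  length(intersect(fa, fb)) / u
}

#' Compare two structures through the match ladder
#'
#' Tiers are tried in order `exact` (identical canonical SMILES), `stereo`
#' (identical after purging stereochemistry), `tautomer` (identical
#' tautomer-invariant key), `charge` (identical after pH 7.4 reionization,
#' or identical InChI once protonation layers are dropped), then `similar`
#' (fingerprint Tanimoto at or above `sim_threshold`), else `none`.  Every
#' tier other than `exact` is approximate and flags the pair for manual
#' checking.
#'
#' @param a,b `gm_structure_forms` objects.
#' @param sim_threshold Tanimoto threshold for the `similar` tier
#'   (default 0.8).
#' @return list with `tier`, `tanimoto` (present for `similar`),
#'   `requires_manual_check`.
#' @export
match_structures <- function(a, b, sim_threshold = 0.8) {
  res <- function(tier, tan = NA_real_) {
    list(tier = tier, tanimoto = tan,
         requires_manual_check = !identical(tier, "exact") && tier != "none")
  }
  if (is.na(a$canonical) || is.na(b$canonical)) return(res("none"))
  if (a$canonical == b$canonical) {
    return(list(tier = "exact", tanimoto = 1, requires_manual_check = FALSE))
  }
  if (!is.na(a$stereo_purged) && identical(a$stereo_purged, b$stereo_purged)) {
    return(res("stereo"))
  }
  if (!is.na(a$tautomer_key) && identical(a$tautomer_key, b$tautomer_key)) {
    return(res("tautomer"))
  }
  charge_eq <- (!is.na(a$ph74) && identical(a$ph74, b$ph74))
  if (!charge_eq && !is.na(a$tautomer_key) && !is.na(b$tautomer_key)) {
    charge_eq <- identical(.inchi_core(a$tautomer_key, drop_protonation = TRUE),
                           .inchi_core(b$tautomer_key, drop_protonation = TRUE))
  }
  if (charge_eq) return(res("charge"))
  if (!is.null(a$fingerprint) && !is.null(b$fingerprint)) {
    tan <- tanimoto(a$fingerprint, b$fingerprint)
    if (tan >= sim_threshold) return(res("similar", tan))
  }
  res("none")
}

#' Hydrogen-blind formula equality
#'
#' Databases disagree on protonation states, so proton-count differences
#' between formulae are neglected: two element maps are equal if they agree
#' on every element except hydrogen.
#'
#' @param fa,fb named integer vectors of element counts (`NULL` = unknown,
#'   which never equals anything).
#' @return logical.
#' @export
formula_equal_ignoring_h <- function(fa, fb) {
  if (is.null(fa) || is.null(fb)) return(FALSE)
  fa <- fa[names(fa) != "H" & fa > 0]
  fb <- fb[names(fb) != "H" & fb > 0]
  if (length(fa) != length(fb)) return(FALSE)
  all(sort(names(fa)) == sort(names(fb))) &&
    all(fa[sort(names(fa))] == fb[sort(names(fb))])
}
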