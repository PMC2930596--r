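# Stoichiometric-consistency validation.
#
# A network is stoichiometrically consistent if every metabolite can be
# assigned a strictly positive molecular mass that is conserved by every
# reaction: exists v >= 1 (componentwise, after scaling) with v %*% N = 0,
# where N is the metabolite x reaction matrix of net coefficients.  When the
# network is inconsistent, the diagnosis proceeds through non-conserved
# metabolites (forced to zero mass in every non-negative conservation
# vector), minimal inconsistent net stoichiometries (one-sided net
# conversions "nothing <-> something") and elementary leakage modes
# (support-minimal reaction combinations y with N y >= 0, N y != 0).
#
# All certificates are computed with an exact rational phase-1/phase-2
# simplex (Bland's rule, guaranteed termination); the floating path runs the
# same pivoting in double arithmetic with a 1e-9 feasibility tolerance.

# ---- exact rational simplex -------------------------------------------------

.rm_reduce <- function(num, den) {
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- .gcd2(num, den)
  g[g == 0] <- 1
  num <- num / g; den <- den / g
  if (any(abs(num) > 2^52) || any(den > 2^52)) {
    stop_gm("exact arithmetic overflow; instance too large for the rational ",
            "path (use method = 'float')")
  }
  list(num = num, den = den)
}

# min cc'x  s.t.  A x = b, x >= 0, all inputs integer-valued numerics.
# Two-phase simplex with Bland's rule; the tableau is exact rational
# (numerator/denominator double matrices, gcd-reduced at every pivot).
# Reduced costs are evaluated in doubles for column selection only, which is
# safe for the well-scaled instances this package generates; feasibility and
# the returned certificate are exact.
.simplex_rat <- function(A, b, cc, exact = TRUE) {
  m <- nrow(A); n <- ncol(A)
  m0 <- m
  stopifnot(length(b) == m, length(cc) == n)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # tableau columns: n original vars, m0 artificials, rhs
  TN <- cbind(A, diag(m), b)
  TD <- matrix(1, m, n + m0 + 1)
  basis <- n + seq_len(m)
  rhs_col <- n + m0 + 1
  tol <- if (exact) 0 else 1e-9

  pivot <- function(r, c) {
    pn <- TN[r, c]; pd <- TD[r, c]
    z <- .rm_reduce(TN[r, ] * pd, TD[r, ] * pn)
    TN[r, ] <<- z$num; TD[r, ] <<- z$den
    for (i in seq_len(m)) {
      if (i == r || TN[i, c] == 0) next
      fn <- TN[i, c]; fd <- TD[i, c]
      z <- .rm_reduce(TN[i, ] * TD[r, ] * fd - fn * TN[r, ] * TD[i, ],
                      TD[i, ] * TD[r, ] * fd)
      TN[i, ] <<- z$num; TD[i, ] <<- z$den
    }
    basis[r] <<- c
  }

  run_phase <- function(cost) {
    repeat {
      cb <- cost[basis]
      red <- cost[seq_len(n + m0)]
      for (i in seq_len(m)) {
        if (cb[i] != 0) {
          red <- red - cb[i] * TN[i, seq_len(n + m0)] / TD[i, seq_len(n + m0)]
        }
      }
      enter <- 0
      for (j in seq_len(n + m0)) {        # Bland: smallest entering index
        if (red[j] < -max(tol, 1e-12)) { enter <- j; break }
      }
      if (enter == 0) return("optimal")
      ratio_i <- 0; best_n <- NA; best_d <- NA
      for (i in seq_len(m)) {
        if (TN[i, enter] / TD[i, enter] > tol) {
          rn <- TN[i, rhs_col] * TD[i, enter]   # ratio rhs_i / T[i,enter]
          rd <- TD[i, rhs_col] * TN[i, enter]
          if (ratio_i == 0 || rn * best_d < best_n * rd ||
              (rn * best_d == best_n * rd && basis[i] < basis[ratio_i])) {
            ratio_i <- i; best_n <- rn; best_d <- rd
          }
        }
      }
      if (ratio_i == 0) return("unbounded")
      pivot(ratio_i, enter)
    }
  }

  # phase 1: drive the artificial variables to zero
  st <- run_phase(c(rep(0, n), rep(1, m0)))
  obj1 <- sum(ifelse(basis > n, TN[, rhs_col] / TD[, rhs_col], 0))
  if (st != "optimal" || obj1 > max(tol, 1e-9)) {
    return(list(status = "infeasible"))
  }
  for (i in seq_len(m)) {                 # pivot leftover artificials out
    if (basis[i] > n) {
      j <- which(TN[i, seq_len(n)] != 0)
      if (length(j)) pivot(i, j[1])
    }
  }
  drop_rows <- which(basis > n)           # redundant constraint rows
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(m), drop_rows)
    TN <- TN[keep, , drop = FALSE]; TD <- TD[keep, , drop = FALSE]
    basis <- basis[keep]; m <- length(keep)
  }
  # phase 2: mask artificial columns so they can never re-enter
  if (m > 0 && m0 > 0) { TN[, n + seq_len(m0)] <- 0; TD[, n + seq_len(m0)] <- 1 }
  st <- run_phase(c(cc, rep(0, m0)))
  if (st != "optimal") return(list(status = st))
  xn <- numeric(n); xd <- rep(1, n)
  for (i in seq_len(m)) {
    if (basis[i] <= n) {
      xn[basis[i]] <- TN[i, rhs_col]
      xd[basis[i]] <- TD[i, rhs_col]
    }
  }
  list(status = "optimal", x = xn / xd, x_num = xn, x_den = xd,
       obj = sum(cc * xn / xd))
}

# ---- matrix construction ----------------------------------------------------

#' Build the stoichiometry matrix of a reconstruction
#'
#' Net coefficient per (metabolite, reaction) = products minus substrates;
#' substrate coefficients are negative.  Metabolites participating in no
#' reaction are omitted.  A metabolite appearing with equal coefficients on
#' both sides keeps its zero net entry (catalytic appearance, warned about);
#' a reaction whose column is entirely zero is dropped with a warning.
#'
#' @param recon a [reconstruction()], or a list with `substrates`/`products`
#'   list-columns in `$reactions`.
#' @param exclude character vector of metabolite local ids to leave out of
#'   the matrix (e.g. molecular hydrogen when mirroring a proton-free
#'   convention).
#' @return a list of class `gm_stoich` with `mat` (metabolite x reaction
#'   numeric matrix), `metabolites`, `reactions`.
#' @export
build_stoich_matrix <- function(recon, exclude = character()) {
  rx <- recon$reactions
  mets <- sort(setdiff(unique(unlist(lapply(seq_len(nrow(rx)), function(i) {
    c(rx$substrates[[i]]$id, rx$products[[i]]$id)
  }))), exclude))
  mat <- matrix(0, length(mets), nrow(rx),
                dimnames = list(mets, rx$local_id))
  for (i in seq_len(nrow(rx))) {
    s <- rx$substrates[[i]]; p <- rx$products[[i]]
    for (k in seq_len(nrow(s))) {
      if (s$id[k] %in% mets) mat[s$id[k], i] <- mat[s$id[k], i] - s$coef[k]
    }
    for (k in seq_len(nrow(p))) {
      if (p$id[k] %in% mets) mat[p$id[k], i] <- mat[p$id[k], i] + p$coef[k]
    }
    both <- intersect(s$id, p$id)
    if (length(both) && any(mat[both, i] == 0)) {
      warning("reaction ", rx$local_id[i], ": catalytic appearance of ",
              paste(both[mat[both, i] == 0], collapse = ", "),
              " kept as zero net entry", call. = FALSE)
    }
  }
  zero_cols <- which(colSums(abs(mat)) == 0)
  if (length(zero_cols)) {
    warning("dropping reaction column(s) with all-zero net stoichiometry: ",
            paste(colnames(mat)[zero_cols], collapse = ", "), call. = FALSE)
    mat <- mat[, -zero_cols, drop = FALSE]
  }
  structure(list(mat = mat, metabolites = rownames(mat),
                 reactions = colnames(mat)),
            class = "gm_stoich")
}

#' @export
print.gm_stoich <- function(x, ...) {
  cat(sprintf("<stoichiometry matrix: %d metabolites x %d reactions>\n",
              length(x$metabolites), length(x$reactions)))
  invisible(x)
}

.stoich_int <- function(m) {
  integerize_columns(m$mat)
}

# integerizing rescales each column by some positive factor s_j; a reaction
# combination found on the scaled matrix must be mapped back through s_j
# before it is reported against the original columns
.rescale_combination <- function(y, S, scaled, orig) {
  s <- vapply(S, function(j) {
    k <- which(orig[, j] != 0)[1]
    scaled[k, j] / orig[k, j]
  }, 0)
  y <- y * s
  r <- rationalize(y)
  l <- 1
  for (d in r$den) l <- l / .gcd2(l, d) * d
  v <- r$num * (l / r$den)
  g <- 0
  for (x in v) g <- .gcd2(g, x)
  if (g > 0) v <- v / g
  v
}

#' Test stoichiometric consistency
#'
#' Searches for a conserved-mass witness `v >= 1` with `v %*% N = 0` as a
#' linear feasibility problem (substituting `v = 1 + w`, `w >= 0`).  On the
#' rational path the witness is exact; the floating path accepts residuals
#' below 1e-9.
#'
#' @param m a `gm_stoich`.
#' @param method `"auto"` (rational up to 20 metabolites, floating beyond),
#'   `"rational"` or `"float"`.
#' @return list with `consistent` (logical), `mass_vector` (named numeric
#'   witness, `NULL` if inconsistent) and `method`.
#' @export
check_consistency <- function(m, method = c("auto", "rational", "float")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (length(m$metabolites) <= 20) "rational" else "float"
  }
  N <- .stoich_int(m)
  nm <- nrow(N); nr <- ncol(N)
  if (nm == 0) {
    return(list(consistent = TRUE, mass_vector = stats::setNames(numeric(0), character(0)),
                method = method))
  }
  # w >= 0 with t(N) w = -t(N) 1
  A <- t(N)
  b <- as.numeric(-colSums(N))
  sol <- .simplex_rat(A, b, rep(0, nm), exact = method == "rational")
  if (sol$status != "optimal") {
    return(list(consistent = FALSE, mass_vector = NULL, method = method))
  }
  v <- 1 + sol$x
  names(v) <- m$metabolites
  list(consistent = TRUE, mass_vector = v, method = method)
}

#' Detect non-conserved metabolites
#'
#' A metabolite is non-conserved when every non-negative conservation vector
#' `v >= 0` with `v %*% N = 0` forces its entry to zero.  Each metabolite is
#' tested by maximizing `v[i]` subject to `v >= 0`, `v <= 1`, `v %*% N = 0`
#' and checking whether the optimum is zero.
#'
#' @param m a `gm_stoich`.
#' @param method as in [check_consistency()].
#' @return character vector of non-conserved metabolite ids (empty iff the
#'   network is consistent).
#' @export
non_conserved_metabolites <- function(m, method = c("auto", "rational", "float")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (length(m$metabolites) <= 20) "rational" else "float"
  }
  N <- .stoich_int(m)
  nm <- nrow(N); nr <- ncol(N)
  if (nm == 0) return(character())
  # variables: v (nm), slack s (nm); constraints t(N) v = 0 ; v + s = 1
  A <- rbind(cbind(t(N), matrix(0, nr, nm)),
             cbind(diag(nm), diag(nm)))
  b <- c(rep(0, nr), rep(1, nm))
  out <- character()
  for (i in seq_len(nm)) {
    cc <- c(rep(0, i - 1), -1, rep(0, nm - i), rep(0, nm))
    sol <- .simplex_rat(A, b, cc, exact = method == "rational")
    vmax <- if (sol$status == "optimal") -sol$obj else 0
    if (vmax <= 1e-9) out <- c(out, m$metabolites[i])
  }
  out
}

# Feasibility of a leakage combination supported on columns S:
#   y free on S, N y >= 0, and a normalization pinning N y != 0.
# extra_row i (optional): require (N y)_i itself to be the normalized positive
# entry.  Returns NULL if infeasible, else exact coprime-integer y over S.
.leak_solve <- function(N, S, pin_row = NULL) {
  nm <- nrow(N)
  ns <- length(S)
  NS <- N[, S, drop = FALSE]
  # variables: yp (ns), ym (ns), t (nm); constraints:
  #   NS yp - NS ym - t = 0        (nm rows)
  #   normalization = 1            (1 row)
  norm_vec <- if (is.null(pin_row)) rep(1, nm) else {
    z <- rep(0, nm); z[pin_row] <- 1; z
  }
  A <- rbind(cbind(NS, -NS, -diag(nm)),
             c(rep(0, 2 * ns), norm_vec))
  b <- c(rep(0, nm), 1)
  sol <- .simplex_rat(A, b, rep(0, ncol(A)), exact = TRUE)
  if (sol$status != "optimal") return(NULL)
  yn <- sol$x_num[seq_len(ns)] * sol$x_den[ns + seq_len(ns)] -
    sol$x_num[ns + seq_len(ns)] * sol$x_den[seq_len(ns)]
  yd <- sol$x_den[seq_len(ns)] * sol$x_den[ns + seq_len(ns)]
  r <- .rm_reduce(yn, yd)
  # scale to coprime integers (positive scaling only: the cone fixes signs)
  l <- 1
  for (d in r$den) l <- l / .gcd2(l, d) * d
  y <- r$num * (l / r$den)
  g <- 0
  for (x in y) g <- .gcd2(g, x)
  if (g > 0) y <- y / g
  y
}

#' Enumerate elementary leakage modes
#'
#' Elementary leakage modes are support-minimal combinations `y` of reaction
#' columns with `N y >= 0` componentwise and `N y != 0`: running the
#' combination creates (one orientation) net mass from nothing.  The list is
#' empty exactly when the network is consistent.  Each mode is canonicalized
#' to coprime integers; the sign pattern is fixed by the cone, so only
#' positive scaling is quotiented out.
#'
#' @param m a `gm_stoich`.
#' @param max_reactions refuse instances with more reactions than this
#'   (support enumeration is exponential); the per-metabolite
#'   [inconsistent_net_stoichiometries()] remains available for larger
#'   networks.
#' @return list of modes, each a list with `combination` (named integer
#'   vector over all reactions) and `net` (named net stoichiometry over
#'   metabolites, one side always empty).
#' @export
elementary_leakage_modes <- function(m, max_reactions = 14) {
  nr <- length(m$reactions)
  if (nr > max_reactions) {
    stop_gm("network has ", nr, " reactions (cap ", max_reactions, "); ",
            "use inconsistent_net_stoichiometries() per metabolite instead")
  }
  N <- .stoich_int(m)
  if (nr == 0 || nrow(N) == 0) return(list())
  found_supports <- list()
  modes <- list()
  for (size in seq_len(nr)) {
    subsets <- utils::combn(nr, size, simplify = FALSE)
    for (S in subsets) {
      if (any(vapply(found_supports, function(fs) all(fs %in% S), TRUE))) next
      y <- .leak_solve(N, S)
      if (is.null(y)) next
      found_supports[[length(found_supports) + 1]] <- S
      comb <- stats::setNames(numeric(nr), m$reactions)
      comb[S] <- .rescale_combination(y, S, N, m$mat)
      net <- as.numeric(m$mat %*% comb)
      names(net) <- m$metabolites
      modes[[length(modes) + 1]] <- list(combination = comb,
                                         net = net[net != 0])
    }
  }
  modes
}

#' Minimal inconsistent net stoichiometries for a non-conserved metabolite
#'
#' Support-minimal reaction combinations whose net stoichiometry is one-sided
#' (`N y >= 0`, i.e. no net substrate) and strictly produces the given
#' metabolite.  The mirrored net-consumption case is the negation of each
#' returned combination.
#'
#' @param m a `gm_stoich`.
#' @param metabolite a metabolite id; must be non-conserved.
#' @param max_reactions as in [elementary_leakage_modes()].
#' @return list of entries with `combination` and `net` as in
#'   [elementary_leakage_modes()]; every `net` has `net[metabolite] > 0` and
#'   no negative entries.
#' @export
inconsistent_net_stoichiometries <- function(m, metabolite, max_reactions = 14) {
  i <- match(metabolite, m$metabolites)
  if (is.na(i)) stop_gm("unknown metabolite: ", metabolite)
  if (!metabolite %in% non_conserved_metabolites(m)) {
    stop_gm(metabolite, " is conserved; minimal inconsistent net ",
            "stoichiometries exist only for non-conserved metabolites")
  }
  nr <- length(m$reactions)
  if (nr > max_reactions) {
    stop_gm("network has ", nr, " reactions (cap ", max_reactions, ")")
  }
  N <- .stoich_int(m)
  found_supports <- list()
  out <- list()
  for (size in seq_len(nr)) {
    for (S in utils::combn(nr, size, simplify = FALSE)) {
      if (any(vapply(found_supports, function(fs) all(fs %in% S), TRUE))) next
      y <- .leak_solve(N, S, pin_row = i)
      if (is.null(y)) next
      found_supports[[length(found_supports) + 1]] <- S
      comb <- stats::setNames(numeric(nr), m$reactions)
      comb[S] <- .rescale_combination(y, S, N, m$mat)
      net <- as.numeric(m$mat %*% comb)
      names(net) <- m$metabolites
      out[[length(out) + 1]] <- list(combination = comb, net = net[net != 0])
    }
  }
  out
}

#' Full consistency report
#'
#' Bundles the consistency verdict, witness, non-conserved metabolites and
#' (for small instances) elementary leakage modes, optionally writing JSON
#' and human-readable text.
#'
#' @param m a `gm_stoich`.
#' @param flag character vector of metabolite ids to call out in the report
#'   when they turn up non-conserved (e.g. molecular hydrogen under a
#'   proton-free convention) without excluding them from the test.
#' @param json,txt optional output file paths.
#' @param max_reactions cap for mode enumeration; above it the report omits
#'   modes.
#' @return list of class `gm_consistency_report`.
#' @export
consistency_report <- function(m, flag = character(), json = NULL, txt = NULL,
                               max_reactions = 14) {
  chk <- check_consistency(m)
  ncm <- if (chk$consistent) character() else non_conserved_metabolites(m)
  modes <- if (!chk$consistent && length(m$reactions) <= max_reactions) {
    elementary_leakage_modes(m, max_reactions)
  } else {
    list()
  }
  rep <- structure(list(
    consistent = chk$consistent,
    method = chk$method,
    mass_vector = chk$mass_vector,
    non_conserved = ncm,
    flagged = intersect(flag, ncm),
    leakage_modes = modes
  ), class = "gm_consistency_report")
  if (!is.null(json)) {
    jsonlite::write_json(list(
      consistent = rep$consistent, method = rep$method,
      mass_vector = as.list(rep$mass_vector %||% stats::setNames(list(), character())),
      non_conserved = rep$non_conserved, flagged = rep$flagged,
      leakage_modes = lapply(rep$leakage_modes, function(md) {
        list(combination = as.list(md$combination[md$combination != 0]),
             net = as.list(md$net))
      })
    ), json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(txt)) {
    lines <- c(
      sprintf("stoichiometric consistency: %s (%s arithmetic)",
              ifelse(rep$consistent, "CONSISTENT", "INCONSISTENT"), rep$method),
      if (!rep$consistent) {
        c(sprintf("non-conserved metabolites (%d): %s", length(ncm),
                  paste(ncm, collapse = ", ")),
          vapply(rep$leakage_modes, function(md) {
            cmb <- md$combination[md$combination != 0]
            paste0("leakage mode: ",
                   paste(sprintf("%+g %s", cmb, names(cmb)), collapse = " "),
                   "  =>  net ",
                   paste(sprintf("%+g %s", md$net, names(md$net)), collapse = " "))
          }, ""))
      }
    )
    writeLines(lines, txt)
  }
  rep
}

#' @export
print.gm_consistency_report <- function(x, ...) {
  cat(sprintf("<consistency report: %s; %d non-conserved; %d leakage modes>\n",
              ifelse(x$consistent, "consistent", "inconsistent"),
              length(x$non_conserved), length(x$leakage_modes)))
  invisible(x)
}
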