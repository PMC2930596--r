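# Internal helpers shared across modules: exact small-rational arithmetic on
# top of double-precision integers, Hill-notation formulas, and misc plumbing.

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- rational numbers ---------------------------------------------------------
# Represented as parallel numeric vectors of integer-valued doubles (num, den),
# den > 0, gcd(|num|, den) = 1.  All magnitudes must stay below 2^53; callers
# work with small stoichiometric coefficients so this is checked, not assumed.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(active <- b > 0)) {
    t <- b[active]
    b[active] <- a[active] %% t
    a[active] <- t
  }
  a
}

rat <- function(num, den = rep(1, length(num))) {
  stopifnot(length(num) == length(den), all(den != 0))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s
  den <- den * s
  g <- .gcd2(num, den)
  g[g == 0] <- 1
  out <- list(num = num / g, den = den / g)
  if (any(abs(out$num) > 2^52) || any(out$den > 2^52)) {
    stop("rational overflow: intermediate values exceed exact double range")
  }
  class(out) <- "gm_rat"
  out
}

rat_add <- function(a, b) rat(a$num * b$den + b$num * a$den, a$den * b$den)
rat_sub <- function(a, b) rat(a$num * b$den - b$num * a$den, a$den * b$den)
rat_mul <- function(a, b) rat(a$num * b$num, a$den * b$den)
rat_div <- function(a, b) {
  if (any(b$num == 0)) stop("rational division by zero")
  rat(a$num * b$den, a$den * b$num)
}
rat_neg <- function(a) rat(-a$num, a$den)
rat_num <- function(a) a$num / a$den
rat_sign <- function(a) sign(a$num)
rat_is_zero <- function(a) a$num == 0

# Continued-fraction rationalization of a double (used to certify floating LP
# witnesses exactly).  max_den bounds the denominator search.
rationalize <- function(x, max_den = 1e6, tol = 1e-9) {
  n <- length(x)
  num <- den <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
    r <- xi
    repeat {
      a <- floor(r)
      p2 <- a * p1 + p0; q2 <- a * q1 + q0
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      if (abs(xi - p1 / q1) < tol * max(1, abs(xi))) break
      if (abs(r - a) < 1e-14) break
      r <- 1 / (r - a)
    }
    num[i] <- p1; den[i] <- q1
  }
  rat(num, den)
}

# Scale the columns of a rational matrix (given as numerics) to coprime
# integers.  Returns integer matrix.
integerize_columns <- function(mat, max_den = 1e6) {
  for (j in seq_len(ncol(mat))) {
    r <- rationalize(mat[, j], max_den = max_den)
    l <- 1
    for (d in r$den) l <- l / .gcd2(l, d) * d
    v <- r$num * (l / r$den)
    g <- 0
    for (x in v) g <- .gcd2(g, x)
    if (g > 0) v <- v / g
    mat[, j] <- v
  }
  mat
}

# -- Hill-notation molecular formulas ----------------------------------------

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "As", "Se", "Br", "Mo", "I", "W", "R"
)

#' Parse a Hill-notation molecular formula
#'
#' Converts a formula string such as `"C6H12O6"` into a named integer vector
#' of element counts.  Hill order is not required on input; unknown element
#' symbols raise an error.
#'
#' @param x character vector of formula strings (`NA`/empty allowed, giving
#'   `NULL` entries).
#' @return for a single string, a named integer vector; for a vector, a list
#'   of such vectors.
#' @export
parse_formula <- function(x) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    parts <- regmatches(s, list(m))[[1]]
    if (!nzchar(s) || sum(nchar(parts)) != nchar(s)) {
      stop("malformed formula: ", s)
    }
    sym <- sub("[0-9]+$", "", parts)
    cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                             sub("^[A-Za-z]+", "", parts), "1"))
    bad <- setdiff(sym, .element_symbols)
    if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    out <- tapply(cnt, sym, sum)
    v <- as.integer(out)
    names(v) <- names(out)
    v
  }
  if (length(x) == 1) one(x) else lapply(x, one)
}

#' Format an element-count map in Hill notation
#'
#' Carbon first, then hydrogen, then all other elements alphabetically
#' (plain alphabetical order if no carbon is present).
#'
#' @param counts named integer vector of element counts.
#' @return a single formula string (`""` for `NULL`/empty input).
#' @export
format_formula <- function(counts) {
  if (is.null(counts) || !length(counts)) return("")
  counts <- counts[counts > 0]
  el <- names(counts)
  if ("C" %in% el) {
    rest <- sort(setdiff(el, c("C", "H")))
    ord <- c("C", intersect("H", el), rest)
  } else {
    ord <- sort(el)
  }
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

# Deterministic local RNG scope: evaluates expr with the given seed, then
# restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Zero-padded local identifiers, widening automatically past 9999.
local_id <- function(prefix, i) {
  sprintf(paste0(prefix, "%04d"), i)
}

stop_gm <- function(...) stop(..., call. = FALSE)
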