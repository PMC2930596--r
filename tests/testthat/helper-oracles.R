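# Independent brute-force oracles and shared fixtures.  Oracles deliberately
# avoid the code paths they check: graph metrics are recomputed with a naive
# BFS, bigram statistics by direct enumeration, and stoichiometric
# diagnostics by bounded integer certificate search.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

get_disc <- function() {
  cached("disc", {
    fx <- discrepancy_fixture()
    state <- integrate_databases(fx$dbA, fx$dbB)
    list(fx = fx, state = state, tiers = assign_tiers(fx$dbA, fx$dbB, state))
  })
}

get_tca <- function() {
  cached("tca", {
    fx <- tca_fixture()
    state <- integrate_databases(fx$dbA, fx$dbB)
    list(fx = fx, state = state, tiers = assign_tiers(fx$dbA, fx$dbB, state))
  })
}

get_gen42 <- function() {
  cached("gen42", {
    fx <- generate_fixture(fixture_spec(seed = 42))
    state <- integrate_databases(fx$dbA, fx$dbB)
    list(fx = fx, state = state, tiers = assign_tiers(fx$dbA, fx$dbB, state))
  })
}

# -- string oracle ------------------------------------------------------------

bf_bigram_dice <- function(a, b) {
  grams <- function(x) {
    x <- gsub("[^a-z0-9]", "", tolower(x))
    if (nchar(x) < 2) return(x)
    vapply(1:(nchar(x) - 1), function(i) substr(x, i, i + 1), "")
  }
  ga <- grams(a); gb <- grams(b)
  if (!length(ga) && !length(gb)) return(1)
  inter <- 0
  gb_pool <- gb
  for (g in ga) {
    hit <- match(g, gb_pool)
    if (!is.na(hit)) { inter <- inter + 1; gb_pool <- gb_pool[-hit] }
  }
  2 * inter / (length(ga) + length(gb))
}

# -- graph oracles (naive BFS on an adjacency matrix) -------------------------

bf_adj <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g)))
  a[a > 1] <- 1
  a
}

bf_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (d[s, w] > lev) { d[s, w] <- lev; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# number of shortest s-t paths and how many pass through each node
bf_path_counts <- function(adj, d, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in which(adj[v, ] > 0)) {
      if (d[s, w] == d[s, v] + 1 && d[w, t] == d[v, t] - 1) walk(c(path, w))
    }
  }
  if (is.finite(d[s, t])) walk(s)
  paths
}

bf_betweenness <- function(g) {
  adj <- bf_adj(g)
  n <- nrow(adj)
  d <- bf_dist(adj)
  comp <- igraph::components(igraph::simplify(g))$membership
  csize <- table(comp)
  out <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || s == t) next
      paths <- bf_path_counts(adj, d, s, t)
      sigma <- length(paths)
      if (!sigma) next
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(paths, function(p) v %in% p, TRUE))
        out[v] <- out[v] + through / sigma
      }
    }
  }
  norm <- vapply(seq_len(n), function(v) {
    Nc <- csize[[as.character(comp[v])]]
    if (Nc > 2) 2 / ((Nc - 1) * (Nc - 2)) else 0
  }, 0)
  stats::setNames(out * norm, rownames(adj))
}

bf_closeness <- function(g) {
  adj <- bf_adj(g)
  d <- bf_dist(adj)
  comp <- igraph::components(igraph::simplify(g))$membership
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    same <- setdiff(which(comp == comp[v]), v)
    if (length(same)) out[v] <- length(same) / sum(d[v, same])
  }
  stats::setNames(out, rownames(adj))
}

bf_clustering <- function(g) {
  adj <- bf_adj(g)
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k >= 2) {
      e <- sum(adj[nb, nb]) / 2
      out[v] <- e / (k * (k - 1) / 2)
    }
  }
  stats::setNames(out, rownames(adj))
}

random_named_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

# -- stoichiometric oracle: bounded integer certificate search ----------------

make_stoich <- function(mat) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("M", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("R", seq_len(ncol(mat)))
  structure(list(mat = mat, metabolites = rownames(mat),
                 reactions = colnames(mat)), class = "gm_stoich")
}

bf_stoich <- function(N, box = 6) {
  if (is.null(rownames(N))) rownames(N) <- paste0("M", seq_len(nrow(N)))
  if (is.null(colnames(N))) colnames(N) <- paste0("R", seq_len(ncol(N)))
  r <- ncol(N)
  combos <- as.matrix(expand.grid(rep(list(seq(-box, box)), r)))
  NY <- combos %*% t(N)
  is_leak <- apply(NY, 1, function(z) all(z >= 0) && any(z > 0))
  leaks <- combos[is_leak, , drop = FALSE]
  leak_net <- NY[is_leak, , drop = FALSE]
  supports <- unique(lapply(seq_len(nrow(leaks)), function(i) {
    which(leaks[i, ] != 0)
  }))
  minimal <- Filter(function(s) {
    !any(vapply(supports, function(o) {
      length(o) < length(s) && all(o %in% s)
    }, TRUE))
  }, supports)
  minimal <- unique(minimal)
  non_conserved <- which(apply(leak_net, 2, function(col) any(col > 0)))
  list(consistent = nrow(leaks) == 0,
       non_conserved = sort(rownames(N)[non_conserved]),
       minimal_supports = lapply(minimal, sort),
       leaks = leaks, leak_net = leak_net)
}

random_stoich <- function(m, r, seed) {
  withr::with_seed(seed, {
    repeat {
      N <- matrix(sample(c(-2:2), m * r, replace = TRUE,
                         prob = c(.15, .2, .3, .2, .15)), m, r)
      if (all(colSums(abs(N)) > 0) && all(rowSums(abs(N)) > 0)) return(N)
    }
  })
}

# reconstruction built from a hidden positive mass assignment: every
# reaction conserves sum(coef * mass) exactly, so consistency must hold
random_conserved_recon <- function(n_met, n_rx, seed) {
  withr::with_seed(seed, {
    mass <- sample(1:5, n_met, replace = TRUE)
    ids <- sprintf("M%02d", seq_len(n_met))
    rx <- .empty_rx_df()
    for (k in seq_len(n_rx)) {
      i <- sample(n_met, 1); j <- sample(setdiff(seq_len(n_met), i), 1)
      if (stats::runif(1) < 0.5) {
        g <- gcd_int(mass[i], mass[j])
        subs <- data.frame(id = ids[i], coef = mass[j] / g)
        prods <- data.frame(id = ids[j], coef = mass[i] / g)
      } else {
        k2 <- sample(setdiff(seq_len(n_met), c(i, j)), 1)
        a <- sample(1:2, 1); b <- sample(1:2, 1)
        subs <- data.frame(id = ids[c(i, j)], coef = c(a, b))
        prods <- data.frame(id = ids[k2],
                            coef = (a * mass[i] + b * mass[j]) / mass[k2])
      }
      row <- data.frame(local_id = sprintf("R%02d", k), id_A = NA_character_,
                        id_B = NA_character_, ec = "", stringsAsFactors = FALSE)
      row$substrates <- list(subs)
      row$products <- list(prods)
      rx <- rbind(rx, row)
    }
    cp <- data.frame(local_id = ids, id_A = ids, name_A = ids,
                     id_B = NA_character_, name_B = NA_character_,
                     evidence = NA_character_, name_probability = NA_real_,
                     structure_tier = NA_character_, stringsAsFactors = FALSE)
    reconstruction("complete", cp, rx)
  })
}

.empty_rx_df <- function() {
  out <- data.frame(local_id = character(), id_A = character(),
                    id_B = character(), ec = character(),
                    stringsAsFactors = FALSE)
  out$substrates <- list()
  out$products <- list()
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# tiny two-reaction inconsistent network from the worked example:
# R1: A <-> B ; R2: A <-> B + C
toy_inconsistent <- function() {
  make_stoich(matrix(c(-1, 1, 0, -1, 1, 1), 3, 2,
                     dimnames = list(c("A", "B", "C"), c("R1", "R2"))))
}

# -- mini databases for unit-testing the engine -------------------------------

mini_db <- function(label, compounds, reactions) {
  source_db(compounds, reactions, label)
}

side_df <- function(...) {
  v <- c(...)
  data.frame(id = names(v), coef = as.numeric(v), stringsAsFactors = FALSE)
}
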