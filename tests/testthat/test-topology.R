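mini_recon <- function(rx_sides) {
  ids <- sort(unique(unlist(rx_sides)))
  cp <- data.frame(local_id = ids, id_A = ids, name_A = ids,
                   id_B = NA_character_, name_B = NA_character_,
                   evidence = NA_character_, name_probability = NA_real_,
                   structure_tier = NA_character_, stringsAsFactors = FALSE)
  rx <- .empty_rx_df()
  for (k in seq_along(rx_sides)) {
    row <- data.frame(local_id = sprintf("R%02d", k), id_A = NA_character_,
                      id_B = NA_character_, ec = "", stringsAsFactors = FALSE)
    row$substrates <- list(data.frame(id = rx_sides[[k]]$s, coef = 1))
    row$products <- list(data.frame(id = rx_sides[[k]]$p, coef = 1))
    rx <- rbind(rx, row)
  }
  reconstruction("complete", cp, rx)
}

test_that("substrates connect to all products, never to co-substrates", {
  g <- build_metabolic_graph(mini_recon(list(list(s = c("A", "B"), p = "C"))))
  el <- apply(igraph::as_edgelist(g), 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(el, c("A-C", "B-C"))
  # a compound on both sides yields a self-loop plus the cross edge
  g2 <- build_metabolic_graph(mini_recon(list(list(s = "A", p = c("A", "B")))))
  expect_equal(sum(igraph::which_loop(g2)), 1)
  expect_true(igraph::are_adjacent(g2, "A", "B"))
  # the same pair contributed by two reactions collapses to one edge
  g3 <- build_metabolic_graph(mini_recon(list(list(s = "A", p = "B"),
                                              list(s = "A", p = "B"),
                                              list(s = "B", p = "A"))))
  expect_equal(igraph::ecount(g3), 1)
})

test_that("isolated compounds stay out of the graph", {
  recon <- mini_recon(list(list(s = "A", p = "B")))
  recon$compounds <- rbind(recon$compounds, data.frame(
    local_id = "Z", id_A = "Z", name_A = "Z", id_B = NA_character_,
    name_B = NA_character_, evidence = NA_character_,
    name_probability = NA_real_, structure_tier = NA_character_,
    stringsAsFactors = FALSE))
  g <- build_metabolic_graph(recon)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
})

test_that("centralities follow the printed closed forms", {
  path3 <- build_metabolic_graph(mini_recon(list(list(s = "a", p = "b"),
                                                 list(s = "b", p = "c"))))
  cb <- graph_betweenness(path3)
  expect_equal(cb[["b"]], 1)
  expect_equal(cb[["a"]], 0)
  cc <- graph_closeness(path3)
  expect_equal(cc[["b"]], 1)
  expect_equal(cc[["a"]], 2 / 3)
  star <- build_metabolic_graph(mini_recon(lapply(1:5, function(i) {
    list(s = "hub", p = paste0("leaf", i))
  })))
  cb_star <- graph_betweenness(star)
  expect_equal(cb_star[["hub"]], 1)
  expect_true(all(cb_star[paste0("leaf", 1:5)] == 0))
  rep_star <- topology_report(star)
  expect_equal(rep_star$centralisation, 1)
  # every node of a clique has closeness 1
  clique <- igraph::make_full_graph(5)
  igraph::V(clique)$name <- letters[1:5]
  expect_true(all(graph_closeness(clique) == 1))
})

test_that("triangle global metrics are exact", {
  tri <- build_metabolic_graph(mini_recon(list(list(s = "a", p = "b"),
                                               list(s = "b", p = "c"),
                                               list(s = "c", p = "a"))))
  rep <- topology_report(tri)
  expect_equal(rep$density, 1)
  expect_equal(rep$clustering_coefficient, 1)
  expect_equal(rep$diameter, 1)
  expect_equal(rep$heterogeneity, 0)
  expect_equal(rep$average_connectivity, 2)
  expect_equal(rep$connected_components, 1)
  expect_equal(rep$average_path_length, 1)
})

test_that("centrality and clustering match brute-force BFS on random graphs", {
  for (sd in 1:50) {
    g <- random_named_graph(n = sample(5:12, 1), p = stats::runif(1, 0.2, 0.6),
                            seed = sd)
    expect_equal(graph_betweenness(g), bf_betweenness(g), tolerance = 1e-12,
                 info = paste("seed", sd))
    expect_equal(graph_closeness(g), bf_closeness(g), tolerance = 1e-12,
                 info = paste("seed", sd))
    expect_equal(graph_clustering(g), bf_clustering(g), tolerance = 1e-12,
                 info = paste("seed", sd))
  }
})

test_that("betweenness mass is invariant under node relabeling", {
  g <- random_named_graph(10, 0.4, seed = 99)
  b1 <- graph_betweenness(g)
  perm <- withr::with_seed(1, sample(igraph::vcount(g)))
  g2 <- igraph::permute(g, perm)
  b2 <- graph_betweenness(g2)
  expect_equal(sort(unname(b1)), sort(unname(b2)), tolerance = 1e-12)
  expect_equal(b1[igraph::V(g)$name], b2[igraph::V(g)$name], tolerance = 1e-12)
})

test_that("global identities hold on fixture-scale graphs", {
  tiers <- get_gen42()$tiers
  for (t in c("core", "complete")) {
    g <- build_metabolic_graph(tiers[[t]], tiers)
    rep <- topology_report(g)
    N <- rep$n_nodes; E <- rep$n_edges; L <- rep$n_self_loops
    expect_equal(rep$average_connectivity, 2 * (E - L) / N)
    expect_equal(rep$density, rep$average_connectivity / (N - 1))
    expect_equal(sum(rep$degree_distribution), N)
    k <- igraph::degree(igraph::simplify(g))
    expect_equal(rep$heterogeneity, sqrt(mean((k - mean(k))^2)) / mean(k))
  }
})

test_that("hub ranking sorts by degree with lexicographic ties", {
  star <- build_metabolic_graph(mini_recon(lapply(1:5, function(i) {
    list(s = "hub", p = paste0("leaf", i))
  })))
  expect_identical(hub_table(star, 1)$node, "hub")
  g <- random_named_graph(12, 0.5, seed = 5)
  ht <- hub_table(g, 12)
  k <- igraph::degree(igraph::simplify(g))
  ord <- order(-k, names(k))
  expect_identical(ht$node, names(k)[ord])
  expect_identical(ht$degree, as.integer(unname(k[ord])))
})

test_that("the shared cofactor tops the cycle fixture's hub table", {
  tca <- get_tca()
  g <- build_metabolic_graph(tca$tiers$complete, tca$tiers)
  top <- hub_table(g, 5)
  expect_identical(top$label[1], "CoA")
  expect_true(all(top$degree == sort(top$degree, decreasing = TRUE)))
  # the hub degree equals the metabolite's substrate-product neighbour count
  k <- igraph::degree(igraph::simplify(g))
  expect_equal(top$degree[1], unname(k[top$node[1]]))
})
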