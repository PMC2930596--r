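test_that("the two-reaction worked example is diagnosed exactly", {
  m <- toy_inconsistent()
  chk <- check_consistency(m)
  expect_false(chk$consistent)
  expect_null(chk$mass_vector)
  expect_identical(non_conserved_metabolites(m), "C")
  modes <- elementary_leakage_modes(m)
  expect_length(modes, 1)
  expect_equal(modes[[1]]$combination, c(R1 = -1, R2 = 1))
  expect_equal(modes[[1]]$net, c(C = 1))       # net conversion: nothing -> C
  nets <- inconsistent_net_stoichiometries(m, "C")
  expect_length(nets, 1)
  expect_equal(nets[[1]]$combination, c(R1 = -1, R2 = 1))
  expect_error(inconsistent_net_stoichiometries(m, "A"), "conserved")
  # with R1 alone the network is consistent with unit masses
  m1 <- make_stoich(matrix(c(-1, 1), 2, 1,
                           dimnames = list(c("A", "B"), "R1")))
  chk1 <- check_consistency(m1)
  expect_true(chk1$consistent)
  expect_equal(chk1$mass_vector, c(A = 1, B = 1))
  expect_length(elementary_leakage_modes(m1), 0)
})

test_that("duplicated reactions yield one minimal combination per support", {
  m <- make_stoich(matrix(c(-1, 1, 0, -1, 1, 1, -1, 1, 1), 3, 3,
                          dimnames = list(c("A", "B", "C"),
                                          c("R1", "R2", "R2b"))))
  modes <- elementary_leakage_modes(m)
  supports <- lapply(modes, function(md) names(md$combination[md$combination != 0]))
  expect_true(list(c("R1", "R2")) %in% supports ||
                any(vapply(supports, identical, TRUE, y = c("R1", "R2"))))
  expect_true(any(vapply(supports, identical, TRUE, y = c("R1", "R2b"))))
  for (md in modes) {
    expect_true(all(md$net >= 0) && any(md$net > 0))
  }
})

test_that("matrix construction follows the products-minus-substrates convention", {
  recon <- random_conserved_recon(4, 3, seed = 2)
  m <- build_stoich_matrix(recon)
  for (i in seq_len(nrow(recon$reactions))) {
    s <- recon$reactions$substrates[[i]]
    p <- recon$reactions$products[[i]]
    for (k in seq_len(nrow(s))) {
      net <- sum(p$coef[p$id == s$id[k]]) - s$coef[k]
      expect_equal(m$mat[s$id[k], i], net)
    }
  }
  # empty reconstruction gives an empty matrix
  cp <- data.frame(local_id = character(), id_A = character(),
                   name_A = character(), id_B = character(),
                   name_B = character(), evidence = character(),
                   name_probability = numeric(), structure_tier = character(),
                   stringsAsFactors = FALSE)
  m0 <- build_stoich_matrix(reconstruction("complete", cp, .empty_rx_df()))
  expect_equal(dim(m0$mat), c(0, 0))
  expect_true(check_consistency(m0)$consistent)
})

test_that("networks built from a hidden positive mass assignment are always consistent", {
  for (sd in 1:12) {
    recon <- random_conserved_recon(n_met = sample(4:8, 1), n_rx = sample(3:7, 1),
                                    seed = sd)
    m <- build_stoich_matrix(recon)
    chk <- check_consistency(m)
    expect_true(chk$consistent, info = paste("seed", sd))
    # the witness is an exact conserved vector with entries >= 1
    v <- chk$mass_vector[m$metabolites]
    expect_true(all(v >= 1))
    resid <- as.numeric(v %*% m$mat)
    expect_true(all(abs(resid) < 1e-9))
    expect_length(non_conserved_metabolites(m), 0)
  }
})

test_that("verdicts agree with bounded brute-force certificate search", {
  run_case <- function(N, label) {
    m <- make_stoich(N)
    bf <- bf_stoich(N)
    expect_identical(check_consistency(m)$consistent, bf$consistent,
                     info = label)
    expect_identical(sort(non_conserved_metabolites(m)), bf$non_conserved,
                     info = label)
    if (ncol(N) <= 4) {
      modes <- elementary_leakage_modes(m)
      impl_supports <- lapply(modes, function(md) {
        sort(unname(which(md$combination != 0)))
      })
      expect_setequal(impl_supports, lapply(bf$minimal_supports, unname))
      # each implementation mode is itself a valid one-sided combination
      for (md in modes) {
        net <- as.numeric(N %*% md$combination)
        expect_true(all(net >= 0) && any(net > 0), info = label)
        g <- Reduce(gcd_int, abs(md$combination[md$combination != 0]))
        expect_equal(g, 1, info = paste(label, "coprime"))
      }
    }
  }
  # exhaustive over 2x2 systems with coefficients in {-2..2}
  vals <- -2:2
  grid <- expand.grid(a = vals, b = vals, c = vals, d = vals)
  n_checked <- 0
  for (i in seq_len(nrow(grid))) {
    N <- matrix(as.numeric(grid[i, ]), 2, 2)
    if (any(colSums(abs(N)) == 0) || any(rowSums(abs(N)) == 0)) next
    n_checked <- n_checked + 1
    run_case(N, paste("2x2 case", i))
  }
  expect_gt(n_checked, 300)
  # random larger instances
  for (sd in 1:25) run_case(random_stoich(3, 3, sd), paste("3x3 seed", sd))
  for (sd in 1:10) run_case(random_stoich(4, 4, 100 + sd), paste("4x4 seed", sd))
})

test_that("positive rescaling of reaction columns changes no verdict", {
  for (sd in c(3, 5)) {
    N <- random_stoich(4, 4, sd)
    m1 <- make_stoich(N)
    N2 <- N %*% diag(c(2, 1 / 3, 5, 1))
    dimnames(N2) <- dimnames(m1$mat)
    m2 <- make_stoich(N2)
    expect_identical(check_consistency(m1)$consistent,
                     check_consistency(m2)$consistent)
    expect_identical(sort(non_conserved_metabolites(m1)),
                     sort(non_conserved_metabolites(m2)))
  }
})

test_that("rational and floating arithmetic paths agree", {
  cases <- c(list(toy_inconsistent()),
             lapply(1:6, function(sd) make_stoich(random_stoich(4, 4, 200 + sd))))
  for (m in cases) {
    expect_identical(check_consistency(m, method = "rational")$consistent,
                     check_consistency(m, method = "float")$consistent)
    expect_identical(sort(non_conserved_metabolites(m, method = "rational")),
                     sort(non_conserved_metabolites(m, method = "float")))
  }
})

test_that("consistency, non-conserved set and leakage modes are jointly coherent", {
  cases <- c(lapply(1:8, function(sd) make_stoich(random_stoich(3, 3, 300 + sd))),
             list(toy_inconsistent(),
                  build_stoich_matrix(random_conserved_recon(5, 4, 77))))
  for (m in cases) {
    consistent <- check_consistency(m)$consistent
    ncm <- non_conserved_metabolites(m)
    modes <- elementary_leakage_modes(m)
    expect_identical(consistent, length(ncm) == 0)
    expect_identical(consistent, length(modes) == 0)
    for (md in modes) {
      expect_true(all(md$net >= 0) || all(md$net <= 0))  # one-sided net
    }
  }
})

test_that("oversized instances are refused with guidance", {
  N <- matrix(rep(c(-1, 1), 20), 2, 20)
  colnames(N) <- paste0("R", 1:20); rownames(N) <- c("A", "B")
  expect_error(elementary_leakage_modes(make_stoich(N)), "per metabolite|cap")
})

test_that("catalytic appearances and all-zero columns are warned about", {
  cp <- data.frame(local_id = c("X", "Y"), id_A = c("X", "Y"),
                   name_A = c("X", "Y"), id_B = NA_character_,
                   name_B = NA_character_, evidence = NA_character_,
                   name_probability = NA_real_, structure_tier = NA_character_,
                   stringsAsFactors = FALSE)
  rx <- .empty_rx_df()
  row <- data.frame(local_id = "R1", id_A = NA_character_,
                    id_B = NA_character_, ec = "", stringsAsFactors = FALSE)
  row$substrates <- list(data.frame(id = c("X", "Y"), coef = c(1, 1)))
  row$products <- list(data.frame(id = c("X", "Y"), coef = c(1, 2)))
  rx <- rbind(rx, row)
  expect_warning(m <- build_stoich_matrix(reconstruction("complete", cp, rx)),
                 "catalytic")
  expect_equal(m$mat["X", 1], 0)
  expect_equal(m$mat["Y", 1], 1)
})
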