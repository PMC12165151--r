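test_that("local minima are exactly the states below all Hamming-1 neighbors", {
  # strong uniform positive fields, no couplings: single monotone funnel
  p <- mem_params(h = rep(3, 5))
  mn <- find_local_minima(exact_distribution(p))
  expect_equal(mn$state, 2^5 - 1L)  # the all-(+1) pattern

  # strong uniform ferromagnet at h = 0: the two aligned ground states
  J <- matrix(1, 4, 4); diag(J) <- 0
  mn2 <- find_local_minima(exact_distribution(mem_params(h = rep(0, 4), J = J)))
  expect_equal(sort(mn2$state), c(0L, 2^4 - 1L))

  # dual-implementation agreement on random instances
  for (s in 1:20) {
    pr <- random_params(6, seed = 300 + s)
    tab <- exact_distribution(pr)
    expect_equal(find_local_minima(tab)$state, oracle_minima(tab$energy))
  }
})

test_that("every landscape has a global minimum among its local minima", {
  for (s in 1:5) {
    pr <- random_params(5, seed = 500 + s)
    tab <- exact_distribution(pr)
    mn <- find_local_minima(tab)
    expect_gte(nrow(mn), 1)
    expect_true(tab$state[which.min(tab$energy)] %in% mn$state)
  }
})

test_that("basin assignment is total, deterministic and descent-consistent", {
  for (s in 1:6) {
    pr <- random_params(6, seed = 600 + s)
    tab <- exact_distribution(pr)
    mn <- find_local_minima(tab)
    basins <- assign_basins(tab, mn)

    # totality: every state assigned; minima map to themselves
    expect_equal(nrow(basins), 2^6)
    expect_false(anyNA(basins$minimum))
    expect_equal(basins$basin_state[basins$is_minimum],
                 basins$state[basins$is_minimum])
    # global minimum maps to itself
    g <- tab$state[which.min(tab$energy)]
    expect_equal(basins$basin_state[basins$state == g], g)
    # basin sizes sum to 2^N
    expect_equal(sum(table(basins$minimum)), 2^6)
    # saddles are flagged states, a subset of assigned ones
    expect_true(all(basins$minimum[basins$saddle] %in% mn$minimum))
  }
})

test_that("states with a unique descent-reachable minimum are assigned to it", {
  for (s in 1:4) {
    pr <- random_params(5, seed = 700 + s)
    tab <- exact_distribution(pr)
    basins <- assign_basins(tab, find_local_minima(tab))
    for (k in tab$state) {
      reach <- oracle_reachable_minima(tab$energy, k)
      if (length(reach) == 1L) {
        expect_equal(basins$basin_state[basins$state == k], reach)
      }
    }
  }
})

test_that("each basin is connected in the Hamming graph", {
  for (s in 1:5) {
    pr <- random_params(6, seed = 800 + s)
    tab <- exact_distribution(pr)
    basins <- assign_basins(tab, find_local_minima(tab))
    n <- 6L
    for (m in unique(basins$minimum)) {
      members <- basins$state[basins$minimum == m]
      # BFS from the minimum within the member set
      start <- basins$basin_state[basins$minimum == m][1]
      seen <- start
      frontier <- start
      while (length(frontier)) {
        nb <- unique(as.vector(sapply(frontier, function(k) {
          bitwXor(k, 2^(0:(n - 1)))
        })))
        frontier <- setdiff(intersect(nb, members), seen)
        seen <- c(seen, frontier)
      }
      expect_setequal(seen, members)
    }
  }
})

test_that("disconnectivity merge energies equal exhaustive minimax barriers", {
  # single-minimum landscape: a single leaf, no merges
  tree1 <- with(list(p = mem_params(h = rep(2, 3))), {
    tab <- exact_distribution(p)
    build_disconnectivity(tab, find_local_minima(tab))
  })
  expect_equal(nrow(tree1$leaves), 1)
  expect_length(tree1$height, 0)
  expect_match(as_newick(tree1), "^\\(m1_s7:0\\);$")

  for (n in c(3, 4)) {
    for (s in 1:6) {
      pr <- random_params(n, seed = 900 + 10 * n + s, range = 0.8)
      tab <- exact_distribution(pr)
      mn <- find_local_minima(tab)
      tree <- build_disconnectivity(tab, mn)
      got <- merge_energies(tree)
      if (nrow(mn) < 2) next
      B <- oracle_minimax_barriers(tab$energy)
      idx <- mn$state + 1
      want <- B[idx, idx]
      diag(want) <- NA
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("merge energies are symmetric, bounded below and ultrametric", {
  for (s in 1:8) {
    pr <- random_params(5, seed = 1000 + s, range = 0.7)
    tab <- exact_distribution(pr)
    mn <- find_local_minima(tab)
    tree <- build_disconnectivity(tab, mn)
    expect_true(all(diff(tree$height) >= -1e-12))
    if (nrow(mn) < 2) next
    me <- merge_energies(tree)
    expect_equal(me, t(me))
    for (a in seq_len(nrow(mn))) {
      for (b in seq_len(nrow(mn))) {
        if (a == b) next
        expect_gte(me[a, b], max(mn$energy[a], mn$energy[b]))
      }
    }
    if (nrow(mn) >= 3) {
      for (a in 1:(nrow(mn) - 2)) for (b in (a + 1):(nrow(mn) - 1)) {
        for (cc in (b + 1):nrow(mn)) {
          expect_lte(me[a, cc], max(me[a, b], me[b, cc]) + 1e-12)
        }
      }
    }
  }
})

test_that("newick export round-trips through a standard tree parser", {
  skip_if_not_installed("ape")
  pr <- make_regime_params("polarized", seed = 3)
  tab <- exact_distribution(pr)
  mn <- find_local_minima(tab)
  tree <- build_disconnectivity(tab, mn)
  phy <- ape::read.tree(text = as_newick(tree))
  expect_equal(length(phy$tip.label), nrow(mn))
})
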