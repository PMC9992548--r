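two_cliques_net <- function(shared = 0, weight = 0.2) {
  # two 4-cliques, optionally sharing `shared` nodes
  p <- 8 - shared
  w <- matrix(0, p, p)
  c1 <- 1:4
  c2 <- (5 - shared):(8 - shared)
  w[c1, c1] <- weight
  w[c2, c2] <- weight
  diag(w) <- 0
  weighted_network(w, paste0("V", seq_len(p)))
}

test_that("spinglass recovers disconnected blocks and minimal graphs", {
  net <- two_cliques_net()
  part <- spinglass_partition(net, n_spins = 5, seed = 1)
  expect_identical(max(part$membership), 2L)
  expect_identical(length(unique(part$membership[1:4])), 1L)
  expect_identical(length(unique(part$membership[5:8])), 1L)
  expect_false(part$membership[1] == part$membership[5])
  # a single positive edge keeps its two nodes together
  w2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  p2 <- spinglass_partition(weighted_network(w2, c("a", "b")),
                            n_spins = 3, seed = 1)
  expect_identical(unname(p2$membership[1]), unname(p2$membership[2]))
  expect_error(spinglass_partition(
    weighted_network(matrix(0, 3, 3), letters[1:3])), "no edges")
})

test_that("spinglass solution beats trivial configurations on planted structure", {
  pl <- planted_block_net()
  part <- spinglass_partition(pl$net, n_spins = 10, seed = 3)
  h <- part$hamiltonian
  expect_lte(h, signed_hamiltonian(pl$net$weights,
                                   rep(1L, 17)))           # one community
  expect_lte(h, signed_hamiltonian(pl$net$weights, 1:17))  # all singletons
  expect_equal(h, signed_hamiltonian(pl$net$weights, part$membership))
})

test_that("clique intensity is the geometric mean of absolute edge weights", {
  net <- two_cliques_net(weight = 0.08)
  expect_equal(clique_intensity(net, 1:4), 0.08)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.1
  w[2, 3] <- w[3, 2] <- 0.4
  w[1, 3] <- w[3, 1] <- 0.1
  net3 <- weighted_network(w, c("a", "b", "c"))
  expect_equal(clique_intensity(net3, c("a", "b", "c")), 0.004^(1 / 3))
  # log-domain oracle on a random signed 5-clique
  set.seed(2)
  w5 <- matrix(0, 5, 5)
  w5[upper.tri(w5)] <- runif(10, 0.01, 0.5) * sample(c(-1, 1), 10, TRUE)
  w5 <- w5 + t(w5)
  net5 <- weighted_network(w5, paste0("n", 1:5))
  expect_equal(clique_intensity(net5, 1:5),
               exp(sum(log(abs(w5[upper.tri(w5)]))) / 10),
               tolerance = 1e-12)
  # missing edge names the offending pair
  w[1, 3] <- w[3, 1] <- 0
  expect_error(clique_intensity(weighted_network(w, c("a", "b", "c")),
                                c("a", "b", "c")), "a and c")
})

test_that("clique percolation handles empty and chained-clique cases", {
  # triangle only: no 4-clique anywhere
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 3] <- w[1, 3] <- 0.3
  w <- pmax(w, t(w))
  oc <- clique_percolation(weighted_network(w, paste0("V", 1:5)), k = 4,
                           I = 0)
  expect_identical(length(oc$communities), 0L)
  expect_true(all(oc$membership_count == 0))
  # two 4-cliques sharing 3 nodes merge into one 5-node community
  net <- two_cliques_net(shared = 3, weight = 0.2)
  oc2 <- clique_percolation(net, k = 4, I = 0.08)
  expect_identical(length(oc2$communities), 1L)
  expect_identical(oc2$communities[[1]], sort(net$node_labels))
  # the threshold at exactly the constant intensity still retains cliques
  oc3 <- clique_percolation(two_cliques_net(weight = 0.08), k = 4, I = 0.08)
  expect_identical(length(oc3$communities), 2L)
})

test_that("clique percolation agrees with subset enumeration on random graphs", {
  set.seed(14)
  for (rep in 1:8) {
    net <- random_sparse_net(12, 30)
    for (k in c(3, 4)) for (I in c(0, 0.08, 0.2)) {
      expect_identical(cpm_canon(clique_percolation(net, k, I), net),
                       brute_cpm(net$weights, k, I))
    }
  }
})

test_that("raising the intensity threshold only prunes community structure", {
  # communities at a higher threshold are nested in (refine) those at a
  # lower one, and the set of covered nodes never grows
  set.seed(15)
  thresholds <- c(0, 0.05, 0.1, 0.2, 0.3)
  for (rep in 1:5) {
    net <- random_sparse_net(12, 34)
    res <- lapply(thresholds, function(I) clique_percolation(net, 3, I))
    for (i in seq_along(thresholds)[-1]) {
      lo <- res[[i - 1]]; hi <- res[[i]]
      for (comm in hi$communities) {
        expect_true(any(vapply(lo$communities,
                               function(big) all(comm %in% big),
                               logical(1))))
      }
      expect_true(all(names(hi$membership_count)[hi$membership_count > 0]
                      %in%
                      names(lo$membership_count)[lo$membership_count > 0]))
    }
  }
})

test_that("clique percolation is invariant under node relabeling", {
  set.seed(16)
  net <- random_sparse_net(12, 32)
  base <- clique_percolation(net, 3, 0.08)
  base_sets <- lapply(base$communities, sort)
  for (rep in 1:10) {
    perm <- sample(12)
    w2 <- net$weights[perm, perm]
    net2 <- weighted_network(w2, net$node_labels[perm])
    oc2 <- clique_percolation(net2, 3, 0.08)
    sets2 <- lapply(oc2$communities, sort)
    expect_setequal(vapply(sets2, paste, character(1), collapse = ","),
                    vapply(base_sets, paste, character(1), collapse = ","))
  }
})
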