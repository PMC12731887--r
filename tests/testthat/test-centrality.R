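toy_partition_net <- function(w = 0.4) {
  codes <- c("A1", "A2", "B1", "B2")
  nodes <- data.frame(code = codes, name = codes,
                      construct = c("X", "X", "Y", "Y"))
  m <- matrix(0, 4, 4, dimnames = list(codes, codes))
  m["A1", "B1"] <- w   # one cross-construct edge
  m["A1", "A2"] <- 0.2 # one within-construct edge
  clpn_network(m, nodes = nodes)
}

test_that("expected influence is the signed row/column sum without the
           autoregressive diagonal", {
  m <- matrix(0, 3, 3)
  diag(m) <- 5           # must never leak into EI
  m[1, 2] <- 0.3; m[1, 3] <- -0.1; m[2, 1] <- 0.2
  net <- clpn_network(m)
  oei <- expected_influence(net, "out", "coeff")
  iei <- expected_influence(net, "in", "coeff")
  expect_equal(unname(oei), c(0.2, 0.2, 0))
  expect_equal(unname(iei), c(0.2, 0.3, -0.1))

  zero <- clpn_network(matrix(0, 5, 5))
  expect_identical(unname(expected_influence(zero, "out")), rep(0, 5))
  expect_identical(unname(expected_influence(zero, "in", "or_minus_1")),
                   rep(0, 5))
})

test_that("total out- and in-influence coincide on either scale", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rnorm(121, sd = 0.2), 11, 11)
    net <- clpn_network(m)
    for (sc in c("coeff", "or_minus_1")) {
      expect_equal(sum(expected_influence(net, "out", sc)),
                   sum(expected_influence(net, "in", sc)))
    }
  }
})

test_that("bridge expected influence sums only cross-construct edges", {
  net <- toy_partition_net(w = 0.4)
  b_out <- bridge_expected_influence(net, direction = "out")
  b_in <- bridge_expected_influence(net, direction = "in")
  expect_equal(unname(b_out), c(0.4, 0, 0, 0))
  expect_equal(unname(b_in), c(0, 0, 0.4, 0))
  # exactly two nonzero bridge values, both |w|
  expect_equal(unname(sort(abs(c(b_out, b_in)[c(b_out, b_in) != 0]))),
               c(0.4, 0.4))

  # no cross-construct edges -> all bridge indices zero
  codes <- c("A1", "A2", "B1", "B2")
  nodes <- data.frame(code = codes, name = codes,
                      construct = c("X", "X", "Y", "Y"))
  m <- matrix(0, 4, 4, dimnames = list(codes, codes))
  m["A1", "A2"] <- 0.5; m["B1", "B2"] <- -0.2
  within_only <- clpn_network(m, nodes = nodes)
  expect_identical(unname(bridge_expected_influence(within_only, direction = "out")),
                   rep(0, 4))

  # a one-construct node set cannot be 2-colored
  expect_error(bridge_expected_influence(clpn_network(matrix(0, 3, 3)),
                                         direction = "out"),
               "two constructs")
})

test_that("bridge influence is bounded by total influence on
           non-negative networks", {
  set.seed(77)
  m <- matrix(abs(rnorm(121, sd = 0.2)), 11, 11)
  net <- clpn_network(m)
  oei <- expected_influence(net, "out")
  boei <- bridge_expected_influence(net, direction = "out")
  expect_true(all(boei <= oei + 1e-12))
  # equality only for nodes with no within-construct out-edges
  toy <- toy_partition_net()
  expect_lt(bridge_expected_influence(toy, direction = "out")["A1"],
            expected_influence(toy, "out")["A1"])
})

test_that("centrality commutes with node permutation", {
  set.seed(41)
  m <- matrix(rnorm(121, sd = 0.2), 11, 11)
  net <- clpn_network(m)
  perm <- sample(11)
  nodes_p <- clpn_nodes()[perm, ]
  net_p <- clpn_network(m[perm, perm], nodes = nodes_p)
  for (fn in list(function(x) expected_influence(x, "out"),
                  function(x) expected_influence(x, "in", "or_minus_1"),
                  function(x) bridge_expected_influence(x, direction = "out"))) {
    expect_equal(unname(fn(net_p)), unname(fn(net)[perm]))
  }
})

test_that("centrality_table standardizes every index across nodes", {
  tab <- centrality_table(fixture_network(), scale = "or_minus_1")
  expect_equal(nrow(tab), 11)
  for (idx in c("z_oei", "z_iei", "z_bridge_oei", "z_bridge_iei")) {
    expect_lt(abs(mean(tab[[idx]])), 1e-12)
    expect_equal(sd(tab[[idx]]), 1)
  }
})

test_that("block_extremum ranks by odds ratio with lexicographic ties", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.3; m[3, 4] <- 0.3; m[2, 1] <- 0.1
  net <- clpn_network(m)
  top <- block_extremum(net, "all", "all", 1)
  expect_equal(unname(top$edge), c("V1", "V2"))  # tie broken by row order
  expect_equal(block_extremum(net, "all", "all", 2)$edge[["from"]], "V3")
  expect_error(block_extremum(net, "all", "all", 4), "rank")

  # agreement with ranked_edges on a non-negative network
  fx <- fixture_network()
  re <- ranked_edges(fx, top_k = 1)
  bx <- block_extremum(fx, "all", "all", 1)
  expect_equal(c(re$from, re$to), unname(bx$edge))
})

test_that("ranked_edges sorts by magnitude and respects top_k", {
  fx <- fixture_network()
  all_edges <- ranked_edges(fx)
  expect_equal(nrow(all_edges), 57)
  expect_true(all(diff(abs(all_edges$coeff)) <= 1e-12))
  expect_equal(nrow(ranked_edges(fx, top_k = 5)), 5)
  expect_equal(nrow(ranked_edges(fx, top_k = 1000)), 57)
  top <- ranked_edges(fx, top_k = 1)
  expect_equal(c(top$from, top$to), c("D3", "F3"))

  # edge set is invariant under node relabeling
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 11)
  net_p <- clpn_network(fx$coeff[perm, perm], nodes = fx$nodes[perm, ])
  e1 <- ranked_edges(fx); e2 <- ranked_edges(net_p)
  expect_setequal(paste(e1$from, e1$to), paste(e2$from, e2$to))
})
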