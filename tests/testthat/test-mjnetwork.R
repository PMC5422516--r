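test_that("recoding collapses indel events and drops constant columns", {
  h <- c(H1 = "AAATCACATGG", H2 = "AAA------GG")
  m <- recode_matrix(h, data.frame(start = 4L, end = 9L))
  expect_equal(ncol(m), 1L)                 # one binary indel character
  expect_equal(sum(m[1, ] != m[2, ]), 1L)   # distance 1: one event
  # identical haplotypes -> zero characters
  expect_equal(ncol(recode_matrix(c(a = "ACGT", b = "ACGT"))), 0L)
  # 2 substitution columns + 1 indel -> 3 characters
  h3 <- c(x = "AC--T", y = "TCGGT", z = "ACGGA")
  m3 <- recode_matrix(h3, data.frame(start = 3L, end = 4L))
  expect_equal(ncol(m3), 3L)
  # overlapping events refuse
  expect_error(recode_matrix(h, data.frame(start = c(4L, 8L), end = c(9L, 10L))),
               "overlapping")
  # a haplotype partially gapped inside an event refuses
  expect_error(recode_matrix(c(a = "A--T", b = "AGGT", c = "AG-T"),
                             data.frame(start = 2L, end = 3L)),
               "partially gapped")
})

test_that("the three-haplotype star gains the median vector AAA", {
  net <- build_mj_network(recode_matrix(c(A = "AAT", B = "ATA", C = "TAA")))
  med <- net$nodes$states[net$nodes$type == "median"]
  expect_equal(med, "AAA")
  # brute force over the full 2^3 state space: AAA is the unique vector
  # achieving total spanning cost 3 (vs 4 without a median)
  obs <- c("AAT", "ATA", "TAA")
  grid <- apply(expand.grid(c("A", "T"), c("A", "T"), c("A", "T")), 1,
                paste, collapse = "")
  costs <- vapply(setdiff(grid, obs), function(x)
    oracle_mst_cost(c(obs, x)), 0)
  expect_equal(oracle_mst_cost(obs), 4)
  expect_equal(names(costs)[costs == 3], "AAA")
  # all three observed nodes link to the median at one step
  expect_true(all(net$edges$weight == 1))
  expect_equal(nrow(net$edges), 3L)
})

test_that("degenerate networks: two haplotypes and one haplotype", {
  n2 <- build_mj_network(recode_matrix(c(X = "AAAA", Y = "TTAA")))
  expect_equal(nrow(n2$edges), 1L)
  expect_equal(n2$edges$weight, 2L)
  n1 <- build_mj_network(recode_matrix(c(S = "ACGT")))
  expect_equal(nrow(n1$nodes), 1L)
  expect_equal(nrow(n1$edges), 0L)
})

test_that("the network is connected and contains a minimum spanning tree", {
  withr::local_seed(405)
  for (rep in 1:25) {
    states <- random_states(sample(2:5, 1), sample(2:8, 1), sample(2:4, 1))
    net <- build_mj_network(recode_matrix(
      stats::setNames(states, paste0("H", seq_along(states)))))
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$id)
    expect_true(igraph::is_connected(g))
    # MST weight within the reported edge set equals the MST weight of the
    # complete graph on the same nodes: a true MST is embedded
    w_complete <- oracle_mst_cost(net$nodes$states)
    w_within <- sum(igraph::E(igraph::mst(g, weights = net$edges$weight))$weight)
    expect_equal(w_within, w_complete)
    # with medians the spanning cost never exceeds the observed-only MST
    expect_true(w_complete <= oracle_mst_cost(
      net$nodes$states[net$nodes$type == "observed"]))
  }
})

test_that("median sets match exhaustive quasi-median enumeration", {
  withr::local_seed(406)
  for (rep in 1:120) {
    states <- random_states(sample(3:5, 1), sample(2:6, 1), sample(2:3, 1))
    m <- recode_matrix(stats::setNames(states, paste0("H", seq_along(states))))
    recoded <- if (ncol(m)) apply(m, 1, paste, collapse = "") else
      rep("", nrow(m))
    net <- build_mj_network(m)
    expect_equal(sort(net$nodes$states), oracle_mj_nodes(unname(recoded)),
                 info = paste(states, collapse = ","))
  }
})

test_that("parental haplotype clusters are linked only through long edges", {
  fx <- get_fixture()
  inv <- get_fixture_inv()
  net <- network_from_inventory(inv, "DUF")
  # brute-force minimum inter-parent distance at DUF from the inventory
  d <- inv$inventory
  di <- d$sequence[d$taxon == "C_dielsianus" & d$locus_id == "DUF"]
  gl <- d$sequence[d$taxon == "C_glaucophyllus" & d$locus_id == "DUF"]
  min_between <- min(outer(di, gl, Vectorize(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]))))
  expect_equal(min_between, 14L)  # the 14 fixed DUF substitutions
  # any path between the two parental clusters traverses >= 14 steps
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$id)
  lab_di <- net$nodes$id[net$nodes$taxa %in%
                           c("C_dielsianus", "C_dielsianus+hybrid")]
  lab_gl <- net$nodes$id[grepl("glaucophyllus", net$nodes$taxa)]
  dist <- igraph::distances(g, v = lab_di, to = lab_gl,
                            weights = igraph::E(g)$weight)
  expect_true(all(dist >= min_between))
})

test_that("exported edge lists and DOT files round-trip the topology", {
  net <- build_mj_network(recode_matrix(c(A = "AAT", B = "ATA", C = "TAA")))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, "tsv")
  el <- utils::read.delim(f)
  expect_equal(nrow(el), 3L)
  expect_named(el, c("node1", "node2", "steps"))
  fd <- withr::local_tempfile(fileext = ".dot")
  export_network(net, fd, "dot")
  dot <- readLines(fd)
  expect_true(any(grepl("graph haplotypes", dot)))
  expect_equal(sum(grepl(" -- ", dot)), 3L)
  expect_error(export_network(net, f, "gml"), "arg")
})
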