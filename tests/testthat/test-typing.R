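# Clustering-type catalog, pair classification, distributions, MCD,
# subnetwork extraction.

test_that("the FFL catalog has 12 types: six 1-node/6-edge and six 2-node/5-edge", {
  catalog <- enumerate_types(motif_ffl())
  expect_equal(nrow(catalog$table), 12)
  one <- catalog$table[catalog$table$shared == 1, ]
  two <- catalog$table[catalog$table$shared == 2, ]
  expect_equal(nrow(one), 6)
  expect_equal(nrow(two), 6)
  expect_true(all(one$n_nodes == 5 & one$n_edges == 6))
  expect_true(all(two$n_nodes == 4 & two$n_edges == 5))
  expect_true(all(catalog$table$id == 1:12))
})

test_that("catalog enumeration agrees with the brute-force identification oracle", {
  catalog <- enumerate_types(motif_ffl())
  want <- oracle_enumerate_types(motif_ffl())
  expect_length(want, 12)
  # every catalog graph matches exactly one oracle graph and vice versa
  hits <- vapply(catalog$graphs, function(g) {
    sum(vapply(want, oracle_iso, logical(1), A = oracle_adjacency(g)))
  }, numeric(1))
  expect_true(all(hits == 1))

  fbl_cat <- enumerate_types(motif_fbl())
  fbl_want <- oracle_enumerate_types(motif_fbl())
  expect_equal(nrow(fbl_cat$table), 2)
  expect_length(fbl_want, 2)
  expect_equal(fbl_cat$table$shared, c(1, 2))
})

test_that("heterologous FFL+FBL catalog matches the exhaustive oracle", {
  het <- enumerate_types(list(motif_ffl(), motif_fbl()),
                         which = "heterologous")
  want <- oracle_enumerate_types(motif_ffl(), motif_fbl())
  expect_equal(nrow(het$table), length(want))
  hits <- vapply(het$graphs, function(g) {
    sum(vapply(want, oracle_iso, logical(1), A = oracle_adjacency(g)))
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("type ids honor the role-pair anchors", {
  catalog <- enumerate_types(motif_ffl())
  tab <- catalog$table
  expect_equal(tab$roles_a[tab$id == 6], "input")
  expect_equal(tab$roles_b[tab$id == 6], "input")
  expect_equal(tab$roles_a[tab$id == 4], "intermediate")
  # duplication anchors: 7 shares {intermediate,output}, 10 {input,output},
  # 12 {input,intermediate}
  expect_equal(tab$roles_a[tab$id == 7], "intermediate+output")
  expect_equal(tab$roles_a[tab$id == 10], "input+output")
  expect_equal(tab$roles_a[tab$id == 12], "input+intermediate")
  # 9 is the three-level hierarchy: {input,intermediate} of one copy on
  # {intermediate,output} of the other
  expect_setequal(c(tab$roles_a[tab$id == 9], tab$roles_b[tab$id == 9]),
                  c("input+intermediate", "intermediate+output"))
})

test_that("classify_pair maps canonical examples to their anchored ids", {
  catalog <- enumerate_types(motif_ffl())
  # shared input -> type 6
  g6 <- net_from_edges(c("a", "b"), c("a", "c"), c("b", "c"),
                       c("a", "d"), c("a", "e"), c("d", "e"))
  i6 <- find_instances(g6, motif_ffl())
  expect_length(i6, 2)
  expect_equal(classify_pair(i6[[1]], i6[[2]], catalog), 6)
  # shared input+intermediate (duplicated output) -> type 12
  g12 <- make_type_fixture(12, 2)$network
  i12 <- find_instances(g12, motif_ffl())
  expect_equal(classify_pair(i12[[1]], i12[[2]], catalog), 12)
  # disjoint pair
  gd <- igraph::disjoint_union(ffl_net(), ffl_net("d", "e", "f"))
  idd <- find_instances(gd, motif_ffl())
  expect_equal(classify_pair(idd[[1]], idd[[2]], catalog), "disjoint")
})

test_that("a k-FFL shared-input star is 100% type 6 with C(k,2) pairs", {
  for (k in c(3, 5)) {
    g <- make_type_fixture(6, k)$network
    td <- type_distribution(g)
    expect_equal(td$n_pairs_clustered, choose(k, 2))
    expect_equal(td$table$fraction[td$table$id == 6], 1)
    expect_equal(sum(td$table$fraction), 1)
  }
})

test_that("a single FFL yields an empty distribution", {
  td <- type_distribution(ffl_net())
  expect_equal(td$n_pairs_clustered, 0)
  expect_equal(sum(td$table$count), 0)
})

test_that("type distribution and MCD agree with brute-force classification on random digraphs", {
  catalog <- enumerate_types(motif_ffl())
  set.seed(99)
  for (rep in 1:15) {
    g <- rand_digraph(sample(10:18, 1), runif(1, 0.15, 0.3))
    td <- type_distribution(g, motif_ffl(), catalog)
    mt <- mcd(g, motif_ffl(), catalog)
    want <- oracle_type_analysis(g, motif_ffl(), catalog)
    expect_equal(td$table$count, unname(as.integer(want$counts)))
    expect_equal(stats::setNames(mt$mcd, mt$node),
                 want$mcd[mt$node])
  }
})

test_that("MCD counts types, not pairs", {
  # hub of a type-6 star joins many pairs of one type -> MCD 1
  g <- make_type_fixture(6, 4)$network
  mt <- mcd(g)
  expect_equal(max(mt$mcd), 1)
  expect_equal(sum(mt$mcd == 1), 1)
  # node in no motif -> MCD 0
  g2 <- igraph::add_vertices(ffl_net(), 1, name = "iso")
  mt2 <- mcd(g2)
  expect_true(all(mt2$mcd == 0))
})

test_that("a node spanning pairs of three distinct types scores MCD 3", {
  # hub h: input of FFLs 1,2 (type 6 pair); with FFL3 sharing {h,b1}
  # (type 12); h is also the output of FFL4 -> pairs of type 3 with 1,2
  g <- net_from_edges(
    c("h", "b1"), c("h", "c1"), c("b1", "c1"),   # F1 = (h, b1, c1)
    c("h", "b2"), c("h", "c2"), c("b2", "c2"),   # F2 = (h, b2, c2)
    c("h", "c3"), c("b1", "c3"),                 # F3 = (h, b1, c3)
    c("x", "y"), c("x", "h"), c("y", "h"))       # F4 = (x, y, h)
  catalog <- enumerate_types(motif_ffl())
  inst <- find_instances(g, motif_ffl())
  expect_length(inst, 4)
  mt <- mcd(g, motif_ffl(), catalog)
  got <- mt$mcd[mt$node == "h"]
  types <- unique(unlist(lapply(seq_len(3), function(i) {
    lapply((i + 1):4, function(j) {
      classify_pair(inst[[i]], inst[[j]], catalog)
    })
  })))
  types <- setdiff(types, "disjoint")
  expect_equal(got, length(unique(types)))
  expect_gte(got, 3)
})

test_that("every clustered pair classifies into the catalog (totality)", {
  catalog <- enumerate_types(motif_ffl())
  set.seed(123)
  for (rep in 1:10) {
    g <- rand_digraph(14, 0.25)
    expect_error(type_distribution(g, motif_ffl(), catalog), NA)
  }
})

test_that("motif subnetwork extraction reports coverage", {
  g <- ffl_net()
  ex <- extract_motif_subnetwork(g)
  expect_equal(ex$node_coverage, 1)
  expect_equal(ex$edge_coverage, 1)
  g2 <- igraph::add_edges(igraph::add_vertices(g, 1, name = "d"),
                          c("c", "d"))
  ex2 <- extract_motif_subnetwork(g2)
  expect_equal(ex2$node_coverage, 3 / 4)
  expect_equal(ex2$edge_coverage, 3 / 4)
  g3 <- net_from_edges(c("a", "b"), c("b", "c"))
  ex3 <- extract_motif_subnetwork(g3)
  expect_equal(ex3$n_instances, 0)
  expect_equal(ex3$node_coverage, 0)
})

test_that("type counts are invariant under node relabeling", {
  set.seed(31)
  g <- rand_digraph(16, 0.25)
  h <- g
  igraph::V(h)$name <- sample(igraph::V(g)$name)
  expect_equal(type_distribution(g)$table$count,
               type_distribution(h)$table$count)
})
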