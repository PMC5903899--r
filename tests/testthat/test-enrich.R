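# Group-size-adjusted enrichment and top-set comparison.

make_mcd_table <- function(mcd_values, nodes = NULL) {
  if (is.null(nodes)) nodes <- paste0("n", seq_along(mcd_values))
  structure(data.frame(node = nodes, mcd = mcd_values,
                       stringsAsFactors = FALSE),
            class = c("mcd_table", "data.frame"))
}

test_that("all-labeled input degenerates to z = 0 with a warning", {
  mt <- make_mcd_table(c(0, 0, 1, 1, 2))
  labs <- stats::setNames(rep(TRUE, 5), mt$node)
  expect_warning(r <- mcd_enrichment(mt, labs), "degenerate")
  expect_true(all(r$z == 0))
})

test_that("a group holding every labeled node is positively enriched", {
  mt <- make_mcd_table(c(rep(0, 8), rep(3, 4)))
  labs <- stats::setNames(c(rep(FALSE, 8), rep(TRUE, 4)), mt$node)
  r <- mcd_enrichment(mt, labs)
  expect_gt(r$z[r$mcd == 3], 0)
  expect_lt(r$z[r$mcd == 0], 0)
})

test_that("hypergeometric moments calibrate against random labeling", {
  set.seed(77)
  mt <- make_mcd_table(rep(c(0, 1, 2, 3), times = c(40, 30, 20, 10)))
  K <- 25
  zmat <- t(vapply(1:400, function(b) {
    labs <- stats::setNames(logical(100), mt$node)
    labs[sample(100, K)] <- TRUE
    mcd_enrichment(mt, labs)$z
  }, numeric(4)))
  # per-group empirical z should be approximately standard
  expect_true(all(abs(colMeans(zmat)) < 0.2))
  expect_true(all(abs(apply(zmat, 2, sd) - 1) < 0.2))
})

test_that("permutation and hypergeometric nulls agree", {
  set.seed(5)
  mt <- make_mcd_table(rep(c(0, 1, 2), times = c(20, 15, 5)))
  labs <- stats::setNames(sample(c(TRUE, FALSE), 40, replace = TRUE),
                          mt$node)
  h <- mcd_enrichment(mt, labs, method = "hypergeometric")
  p <- mcd_enrichment(mt, labs, method = "permutation", n_perm = 4000,
                      seed = 8)
  expect_equal(p$expected, h$expected, tolerance = 0.05)
  expect_equal(p$sd, h$sd, tolerance = 0.1)
})

test_that("unlabeled scored nodes are an error; stray label keys warn", {
  mt <- make_mcd_table(c(0, 1, 2))
  expect_error(mcd_enrichment(mt, c(n1 = TRUE, n2 = FALSE)),
               "without a label")
  expect_warning(
    mcd_enrichment(mt, c(n1 = TRUE, n2 = FALSE, n3 = TRUE, zz = TRUE)),
    "matching no scored node")
})

test_that("identical measures give full overlap and no unique hits", {
  m <- data.frame(node = paste0("n", 1:10), mcd = 10:1, degree = 10:1,
                  betweenness = 10:1,
                  label = rep(c(TRUE, FALSE), 5))
  r <- top_set_comparison(m, 4)
  expect_true(all(r$overlap == 4))
  expect_true(all(r$per_measure$unique_hits == 0))
  expect_true(all(r$per_measure$labeled_hits ==
                    r$per_measure$labeled_hits[1]))
})

test_that("disjoint top sets make every hit unique", {
  m <- data.frame(node = paste0("n", 1:9),
                  mcd = c(3, 2, 1, 0, 0, 0, 0, 0, 0),
                  degree = c(0, 0, 0, 3, 2, 1, 0, 0, 0),
                  betweenness = c(0, 0, 0, 0, 0, 0, 3, 2, 1),
                  label = rep(TRUE, 9))
  r <- top_set_comparison(m, 3)
  expect_equal(r$per_measure$unique_hits, r$per_measure$labeled_hits)
})

test_that("threshold ties are all included and the effective k reported", {
  m <- data.frame(node = paste0("n", 1:6),
                  mcd = c(5, 4, 3, 3, 3, 1), degree = 6:1,
                  betweenness = 6:1, label = rep(TRUE, 6))
  r <- top_set_comparison(m, 3)
  expect_equal(r$per_measure$effective_k[r$per_measure$measure == "mcd"], 5)
  expect_error(top_set_comparison(m, 10), "between 1 and")
})

test_that("Venn region counts match a brute-force set computation", {
  set.seed(19)
  n <- 40
  m <- data.frame(node = paste0("n", 1:n), mcd = sample(0:12, n, TRUE),
                  degree = sample(1:60, n, TRUE),
                  betweenness = runif(n),
                  label = sample(c(TRUE, FALSE), n, TRUE))
  k <- 10
  r <- top_set_comparison(m, k)
  sel <- lapply(c("mcd", "degree", "betweenness"), function(ms) {
    thr <- sort(m[[ms]], decreasing = TRUE)[k]
    m$node[m[[ms]] >= thr]
  })
  labeled <- m$node[m$label]
  for (pat in names(r$venn)) {
    bits <- as.integer(strsplit(pat, "")[[1]])
    region <- labeled
    for (i in 1:3) {
      region <- if (bits[i]) intersect(region, sel[[i]])
                else setdiff(region, sel[[i]])
    }
    expect_equal(unname(r$venn[[pat]]), length(region))
  }
})

test_that("node_metrics assembles MCD, degree, betweenness, and labels", {
  g <- make_type_fixture(6, 3)$network
  labs <- data.frame(node = igraph::V(g)$name,
                     label = rep(c("true", "false"),
                                 length.out = igraph::vcount(g)))
  m <- node_metrics(g, motif_ffl(), labs)
  expect_setequal(names(m), c("node", "mcd", "degree", "betweenness",
                              "label"))
  expect_equal(m$mcd[m$node == "a"], 1)
  expect_equal(m$degree[m$node == "a"], 6)
})
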