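test_that("edge-list loading drops self-loops and duplicate edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#from\tto", "a\tb", "b\tc", "b\ta", "c\tc"), f)
  expect_message(net <- load_edge_list(f), "dropped 2")
  expect_equal(net$nodes, c("a", "b", "c"))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(unname(net$edges), rbind(c("a", "b"), c("b", "c")))
})

test_that("edge-list parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2", "g3\tg4\tg5"), f)
  expect_error(load_edge_list(f), "line 2")
  writeLines(c("# only a comment"), f)
  expect_error(load_edge_list(f), "empty")
})

test_that("SIF dialect ignores the relation token", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("g1 pp g2", "g2 pp g3"), f)
  net <- load_edge_list(f, dialect = "sif")
  expect_equal(net$nodes, c("g1", "g2", "g3"))
  expect_equal(nrow(net$edges), 2L)
  writeLines("g1 g2", f)
  expect_error(load_edge_list(f, dialect = "sif"), "expected 3 fields")
})

test_that("a written network round-trips identically", {
  study <- std_study()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(study$network, f)
  expect_identical(load_edge_list(f), study$network)
  # and a small 10-row synthetic one
  small <- gene_network(cbind(sprintf("a%d", 1:10), sprintf("b%d", 1:10)))
  write_edge_list(small, f)
  expect_identical(load_edge_list(f), small)
})

test_that("largest component keeps the biggest piece, ties to smallest id", {
  net <- gene_network(rbind(c("a", "b"), c("c", "d"), c("d", "e")))
  expect_equal(largest_component(net)$nodes, c("c", "d", "e"))
  # connected graph unchanged
  expect_identical(largest_component(path3_net()), path3_net())
  # equal-size tie: component containing lexicographically smallest node wins
  tie <- gene_network(rbind(c("c", "d"), c("a", "b")))
  expect_equal(largest_component(tie)$nodes, c("a", "b"))
  # idempotent
  lcc <- largest_component(net)
  expect_identical(largest_component(lcc), lcc)
})

test_that("transition matrix is the degree-normalized adjacency", {
  A <- transition_matrix(path3_net(), sparse = FALSE)
  # column of the middle node splits evenly onto its two neighbors
  expect_equal(unname(A[, "b"]), c(0.5, 0, 0.5))
  expect_equal(unname(A[, "a"]), c(0, 1, 0))
  expect_equal(unname(A[, "c"]), c(0, 1, 0))
  # single edge
  A2 <- transition_matrix(gene_network(rbind(c("a", "b"))), sparse = FALSE)
  expect_equal(unname(A2), rbind(c(0, 1), c(1, 0)))
})

test_that("transition matrix columns sum to one, dense and sparse agree", {
  set.seed(11)
  for (i in 1:5) {
    net <- random_connected_net(40)
    As <- transition_matrix(net, sparse = TRUE)
    Ad <- transition_matrix(net, sparse = FALSE)
    expect_lt(max(abs(Matrix::colSums(As) - 1)), 1e-12)
    expect_true(all(Ad >= 0))
    expect_equal(as.matrix(As), Ad, tolerance = 1e-15)
  }
})

test_that("transition matrix rejects isolated nodes with guidance", {
  net <- gene_network(rbind(c("a", "b")), nodes = c("a", "b", "z"))
  expect_error(transition_matrix(net), "largest connected component")
})

test_that("node relabeling permutes the transition matrix accordingly", {
  set.seed(7)
  net <- random_connected_net(30)
  relabel <- stats::setNames(sprintf("z%04d", seq_along(net$nodes)),
                             net$nodes)
  net2 <- gene_network(cbind(relabel[net$edges[, 1L]],
                             relabel[net$edges[, 2L]]))
  A1 <- transition_matrix(net, sparse = FALSE)
  A2 <- transition_matrix(net2, sparse = FALSE)
  perm <- match(net2$nodes, unname(relabel[net$nodes]))
  expect_equal(unname(A2), unname(A1[perm, perm]))
})

test_that("bridge subnetwork keeps exactly the shortest-path nodes", {
  # path a-b-c between {a} and {c}
  sub <- bridge_subnetwork(path3_net(), "a", "c", max_path_len = 2)
  expect_equal(sub$nodes, c("a", "b", "c"))
  # star: only the x-h-y path, z excluded
  sub2 <- bridge_subnetwork(star_net(), "x", "y", max_path_len = 2)
  expect_equal(sub2$nodes, c("h", "x", "y"))
  # no path within budget: empty with a warning
  expect_warning(
    sub3 <- bridge_subnetwork(path3_net(), "a", "c", max_path_len = 1),
    "no path")
  expect_equal(length(sub3$nodes), 0L)
  # both sets off-network
  expect_error(bridge_subnetwork(path3_net(), "q", "w", 2), "neither")
})

test_that("gene-set and association files round-trip", {
  sets <- list(d1 = c("g1", "g2"), d2 = c("g3"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, f)
  got <- read_gene_sets(f)
  expect_equal(got[order(names(got))], sets, ignore_attr = TRUE)
  expect_equal(unname(attr(got, "descriptions")), c("na", "na"))
  writeLines("d1\tonly-description", f)
  expect_error(read_gene_sets(f), "line 1")

  assoc <- association_table(c("r2", "r1"), c("d1", "d2"))
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_associations(assoc, fa)
  expect_identical(read_associations(fa), assoc)
  expect_equal(nrow(read_associations(
    { writeLines("#drug\tdisease", fa); fa })), 0L)
})
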