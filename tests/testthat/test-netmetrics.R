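test_that("connectance counts directed links over S^2", {
  sp <- tibble::tibble(id = 1:5, r = 0.1, s = 1)
  expect_equal(connectance(community(sp)), 0)
  sp2 <- tibble::tibble(id = 1:2, r = 0.1, s = 1)
  M <- matrix(0, 2, 2); M[1, 2] <- M[2, 1] <- 0.1
  comm <- community(sp2, M = M)
  expect_equal(connectance(comm), 0.5) # L = 2, S = 2
  expect_equal(2 * connectance(comm), 1) # complexity S * C
  # CR pair also contributes two directed links
  Pp <- matrix(0, 2, 2); Pm <- matrix(0, 2, 2)
  Pp[1, 2] <- 0.1; Pm[2, 1] <- 0.2
  expect_equal(connectance(community(sp2, Pplus = Pp, Pminus = Pm)), 0.5)
  # never exceeds (S-1)/S without self-loops
  set.seed(3)
  for (k in 1:10) {
    cm <- random_community(sample(2:8, 1), p_link = 1)
    expect_lte(connectance(cm), (n_species(cm) - 1) / n_species(cm))
  }
})

test_that("undirected projection keeps isolated nodes and sums weights", {
  sp <- tibble::tibble(id = 1:3, r = 0.1, s = 1)
  Pp <- matrix(0, 3, 3); Pm <- matrix(0, 3, 3)
  Pp[1, 2] <- 0.1; Pm[2, 1] <- 0.3
  comm <- community(sp, Pplus = Pp, Pminus = Pm)
  g <- to_undirected(comm, weighted = TRUE)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.4)
  expect_identical(unname(igraph::degree(g)), c(1, 1, 0))
  set.seed(4)
  cm <- random_community(8, p_link = 0.5)
  expect_lte(igraph::ecount(to_undirected(cm)), 8 * 7 / 2)
})

test_that("degree entropy matches hand-computed cases", {
  ring <- igraph::make_ring(6)
  expect_equal(degree_entropy(ring), 0) # regular graph: one degree class
  # degrees {1,1,2,2}: two equal classes -> ln 2
  path4 <- igraph::make_graph(c(1,2, 2,3, 3,4), directed = FALSE)
  expect_equal(degree_entropy(path4), log(2))
  # entropy bounded by log of the number of distinct degrees
  set.seed(5)
  g <- igraph::sample_gnp(30, 0.2)
  expect_lte(degree_entropy(g), log(length(unique(igraph::degree(g)))) + 1e-12)
  # invariant under relabeling
  perm <- sample(30)
  expect_equal(degree_entropy(igraph::permute(g, perm)), degree_entropy(g))
})

test_that("modularity formula matches closed forms", {
  # two disjoint triangles, true partition: m = 6, L_c = 3, k_c = 6 -> 0.5
  g <- two_cliques(3)
  part <- rep(1:2, each = 3)
  expect_equal(modularity_score(g, part), 0.5)
  # two disjoint K_n: 0.5 for all n
  for (n in c(2, 4, 7)) {
    expect_equal(modularity_score(two_cliques(n), rep(1:2, each = n)), 0.5)
  }
  # single community: 1 - epsilon
  g1 <- igraph::make_full_graph(5)
  expect_equal(modularity_score(g1, rep(1, 5)), 0)
  expect_equal(modularity_score(g1, rep(1, 5), epsilon = 0.5), 0.5)
  # complete graph, singletons: negative
  expect_lt(modularity_score(g1, 1:5), 0)
  # invariant under partition relabeling
  set.seed(6)
  g <- igraph::sample_gnp(20, 0.3)
  part <- sample(1:3, 20, replace = TRUE)
  relab <- c(3, 1, 2)[part]
  expect_equal(modularity_score(g, part), modularity_score(g, relab))
})

test_that("louvain recovers planted modules deterministically", {
  g <- two_cliques(3)
  part <- louvain_partition(g, seed = 1)
  expect_identical(length(unique(part)), 2L)
  expect_identical(part[1], part[2])
  expect_identical(part[1], part[3])
  expect_false(part[1] == part[4])
  expect_equal(modularity_score(g, part), 0.5)
  expect_identical(louvain_partition(g, seed = 7), louvain_partition(g, seed = 7))
  # at least as good as the single-community baseline
  set.seed(8)
  g2 <- igraph::sample_gnp(25, 0.15)
  g2 <- igraph::delete_vertices(g2, which(igraph::degree(g2) == 0))
  part2 <- louvain_partition(g2, seed = 2)
  expect_gte(modularity_score(g2, part2),
             modularity_score(g2, rep(1, igraph::vcount(g2))))
})

test_that("ER nulls match the target edge count and complete graphs give H = 0", {
  nulls <- er_null(10, n_edges = 45, n_rep = 5, seed = 1) # p = 1: complete
  expect_true(all(nulls$H == 0))
  expect_true(all(nulls$n_edges == 45))
  set.seed(2)
  nulls <- er_null(20, n_edges = 60, n_rep = 200)
  se <- sd(nulls$n_edges) / sqrt(200)
  expect_lt(abs(mean(nulls$n_edges) - 60), 3 * max(se, 1e-9))
  # seeded reproducibility
  expect_identical(er_null(12, 20, n_rep = 5, seed = 3),
                   er_null(12, 20, n_rep = 5, seed = 3))
})

test_that("external edge lists and matrix exports round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(node_i = c(1, 2, 3), node_j = c(2, 3, 1),
                                  weight = c(0.5, 0.2, 0.1)), path)
  g <- read_network_tsv(path)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(degree_entropy(g), 0) # triangle is regular
  set.seed(12)
  comm <- random_community(5, p_link = 0.6)
  dir <- withr::local_tempdir()
  write_community_matrices(comm, dir)
  M <- as.matrix(utils::read.csv(file.path(dir, "M.csv"), row.names = 1))
  expect_equal(unname(M), comm$M)
})

test_that("effective increase is a relative elevation", {
  expect_equal(effective_increase(2, 2), 0)
  expect_equal(effective_increase(4, 2), 1)
  expect_error(effective_increase(1, 0), "zero null")
})

test_that("ER networks score near zero against their own null", {
  set.seed(9)
  scores <- replicate(40, {
    g <- igraph::sample_gnp(25, 0.2)
    H <- degree_entropy(g)
    nulls <- er_null(25, igraph::ecount(g), n_rep = 20)
    effective_increase(H, mean(nulls$H))
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se + 0.02)
})

test_that("metrics_report assembles all structural summaries", {
  set.seed(10)
  comm <- random_community(12, p_link = 0.4)
  rep1 <- metrics_report(comm, n_null = 20, seed = 5)
  expect_equal(rep1$complexity, rep1$S * rep1$connectance)
  expect_gte(rep1$H, 0)
  expect_true(is.finite(rep1$Mod))
  expect_true(is.finite(rep1$H_score))
  expect_equal(rep1$prop_m + rep1$prop_c + rep1$prop_cr, 1)
  rep2 <- metrics_report(comm, n_null = 20, seed = 5)
  expect_equal(rep1, rep2)
})
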