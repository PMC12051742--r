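test_that("SNP blocks are consecutive, contig-bounded, trailing-flagged", {
  sites <- tibble::tibble(
    contig = rep(c("c1", "c2"), c(120, 30)),
    pos = c(seq_len(120) * 10, seq_len(30) * 10))
  b <- partition_blocks(sites, block_size = 50)
  expect_identical(nrow(b), 4L)
  expect_identical(b$n_snps, c(50L, 50L, 20L, 30L))
  expect_identical(b$complete, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(b$contig[1:3] == "c1"))
  expect_identical(b$contig[4], "c2")  # blocks never span contigs
  expect_identical(nrow(partition_blocks(sites[0, ])), 0L)
  expect_error(partition_blocks(sites[c(2, 1), ]), "sorted")
})

test_that("NJ on additive distances recovers the generating quartet", {
  # sequences engineered so distances are additive: ((h1,h2),(h3,h4))
  # an explicitly additive design: every pendant edge carries private
  # mutations, the internal edge is shared by the (h3, h4) cherry, and
  # p-distances stay small (< 0.05) so the distance correction is
  # near-linear and preserves additivity
  S <- 300
  base <- rep(0L, S)
  h1 <- base; h1[1:6] <- 1L; h1[13:20] <- 1L
  h2 <- base; h2[7:12] <- 1L; h2[13:20] <- 1L
  h3 <- base; h3[21:30] <- 1L; h3[31:36] <- 1L
  h4 <- base; h4[21:30] <- 1L; h4[37:42] <- 1L
  og <- base; og[290:297] <- 1L
  H <- rbind(h1, h2, h3, h4)
  g <- make_geno(H, pop = c("P", "P", "Q", "Q"), pos = 1:S,
                 contig_len = S, outgroup = og)
  # 4-point condition confirms additivity of the engineered matrix
  d <- as.matrix(dist(H, method = "manhattan"))
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  expect_lt(sums[1], min(sums[2:3]))
  expect_equal(sums[2], sums[3])
  tr <- build_block_tree(g, 1, S)
  expect_true(ape::is.monophyletic(tr, c("P_1_a", "P_1_b")))
  expect_true(ape::is.monophyletic(tr, c("Q_2_a", "Q_2_b")))
  expect_true(all(tr$edge.length >= 0))
  # the outgroup is a child of the root after rooting
  root_kids <- tr$edge[tr$edge[, 1] == length(tr$tip.label) + 1, 2]
  expect_true(match("OUT", tr$tip.label) %in% root_kids)
})

test_that("identical sequences collapse to a star tree", {
  H <- matrix(0L, 4, 10)
  g <- make_geno(H, pop = c("P", "P", "Q", "Q"), pos = 1:10,
                 outgroup = rep(0L, 10))
  tr <- build_block_tree(g, 1, 10)
  expect_identical(tr$Nnode, 1L)
  expect_true(all(tr$edge.length == 0))
})

test_that("the distance cascade is recorded per block", {
  ds <- tiny_gws_dataset()
  bt <- block_trees(ds$geno, block_size = 50)
  expect_identical(length(bt$trees), nrow(bt$blocks))
  models <- vapply(bt$trees, function(t) attr(t, "dist_model"),
                   character(1))
  expect_true(all(models %in% c("TN93", "K80", "JC69", "raw")))
})

test_that("perfectly sorted trees put all weight on their topology", {
  tr <- ape::read.tree(text = "(((A_1_a,A_1_b),(B_1_a,B_1_b)),C_1_a);")
  tr <- ape::compute.brlen(tr)
  w <- topology_weights(tr, c("A", "B", "C"), mode = "exact")
  expect_equal(w$weight[w$topology == "((A,B),C)"], 1)
  expect_equal(sum(w$weight), 1)
})

test_that("interleaved cherries still weight the sister pair fully", {
  # every sampled (a_i, b_j) pair coalesces before c joins
  tr <- ape::read.tree(text = "(((a1,b1),(a2,b2)),c);")
  tr <- ape::compute.brlen(tr)
  tmap <- list(A = match(c("a1", "a2"), tr$tip.label) - 1L,
               B = match(c("b1", "b2"), tr$tip.label) - 1L,
               C = match("c", tr$tip.label) - 1L)
  res <- crowdemog:::cpp_topo_weights(
    crowdemog:::phylo_to_parent(tr), unname(tmap), TRUE, 0, 1e6, 1)
  expect_identical(res$n_combinations, 4)
  expect_identical(as.character(res$topology), "((0,1),2)")
  expect_identical(as.numeric(res$count), 4)
})

test_that("sampled weights converge on exact weights", {
  gws <- build_gws_model()
  trees <- simulate_tree_set(gws, 6, seed = 41,
                             samples = c(SPA = 6, EURw = 6, EURns = 6))
  for (tr in trees) {
    we <- topology_weights(tr, c("SPA", "EURw", "EURns"), mode = "exact")
    ws <- topology_weights(tr, c("SPA", "EURw", "EURns"),
                           mode = "sampled", n_iter = 10000, seed = 5)
    expect_lt(max(abs(we$weight - ws$weight)), 0.02)
    expect_equal(sum(we$weight), 1)
  }
})

test_that("weight tables order the canonical trio columns", {
  gws <- build_gws_model()
  gs <- sim_genealogy_set(gws, 30, seed = 6, outgroup = TRUE)
  tab <- topology_weight_table(gs, c("SPA", "EURw", "EURns"),
                               n_iter = 1500, seed = 2)
  expect_identical(names(tab), c("block", "topo1", "topo2", "topo3"))
  expect_equal(rowSums(tab[, -1]), rep(1, 30))
  al <- attr(tab, "topologies")
  expect_identical(unname(al["topo2"]), "(SPA,(EURw,EURns))")
  expect_identical(unname(al["topo3"]), "((SPA,EURw),EURns)")
})

test_that("the exact-mode cap instructs sampled mode", {
  gws <- build_gws_model()
  tr <- simulate_tree_set(gws, 1, seed = 77)[[1]]
  expect_error(topology_weights(tr, c("SPA", "EURw", "EURns"),
                                mode = "exact", cap = 100),
               "sampled")
})

test_that("ternary binning covers the simplex with k^2 cells", {
  w <- tibble::tibble(topo1 = c(1 / 3, 1, 0),
                      topo2 = c(1 / 3, 0, 0),
                      topo3 = c(1 / 3, 0, 1))
  gr <- ternary_bin(w, k = 20)
  expect_identical(nrow(gr), 400L)
  expect_identical(sum(gr$count), 3L)
  # the centroid block sits in a central cell, corners in corner cells
  centre <- gr[gr$count > 0 & gr$a >= 6 & gr$a <= 7, ]
  expect_identical(nrow(centre), 1L)
  corner_a <- gr[gr$count > 0 & gr$a == 19, ]
  expect_identical(nrow(corner_a), 1L)
  expect_error(ternary_bin(tibble::tibble(a = 0.5, b = 0.2, c = 0.2)),
               "normalisation")
  expect_identical(nrow(ternary_bin(w, k = 12)), 144L)
})

test_that("grid comparison rescales and reports the L1 distance", {
  w1 <- tibble::tibble(topo1 = rep(1, 5), topo2 = 0, topo3 = 0)
  w2 <- tibble::tibble(topo1 = 0, topo2 = 0, topo3 = rep(1, 10))
  g1 <- ternary_bin(w1); g2 <- ternary_bin(w2)
  same <- compare_ternary(g1, g1)
  expect_identical(attr(same, "L1"), 0)
  cross <- compare_ternary(g1, g2)
  expect_identical(attr(cross, "L1"), 10)  # 2 x observed mass of 5
  expect_error(compare_ternary(g1, ternary_bin(w2, k = 10)),
               "subdivision")
})
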