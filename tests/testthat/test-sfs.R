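test_that("folding matches the brute-force oracle on random small panels", {
  set.seed(42)
  for (rep in 1:60) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    S <- sample(5:40, 1)
    iA <- sample(0:nA, S, replace = TRUE)
    iB <- sample(0:nB, S, replace = TRUE)
    H <- rbind(
      vapply(seq_len(S), function(s) as.integer(seq_len(nA) <= iA[s]),
             integer(nA)) |> matrix(nrow = nA),
      vapply(seq_len(S), function(s) as.integer(seq_len(nB) <= iB[s]),
             integer(nB)) |> matrix(nrow = nB))
    pop <- c(rep("A", nA), rep("B", nB))
    js <- folded_jsfs(H, "A", "B", pop = pop)
    expect_equal(unname(unclass(js$matrix)),
                 brute_fold_jsfs(iA, iB, nA, nB))
  }
})

test_that("a (2,1) site in a 2+2-haploid panel folds into cell (0,1)", {
  H <- matrix(c(1, 1,   # popA haplotypes carry the alternate twice
                1, 0),  # popB once
              ncol = 1)
  js <- folded_jsfs(H, "A", "B", pop = c("A", "A", "B", "B"))
  expect_equal(js$matrix["dA0", "dB1"], 1)
  expect_equal(js$n_sites, 1)
})

test_that("monomorphic input yields an all-zero folded matrix with masked corners", {
  H <- matrix(0L, 4, 10)
  js <- folded_jsfs(H, "A", "B", pop = c("A", "A", "B", "B"))
  expect_true(all(js$matrix == 0))
  H2 <- matrix(1L, 4, 10)  # fixed derived folds into the masked corner
  js2 <- folded_jsfs(H2, "A", "B", pop = c("A", "A", "B", "B"))
  expect_true(all(js2$matrix == 0))
})

test_that("the folded spectrum of the 15x15-diploid panel is 31 x 31", {
  ds <- tiny_gws_dataset()
  js <- folded_jsfs(ds$geno, "SPA", "EURw")
  expect_identical(dim(js$matrix), c(31L, 31L))
  js2 <- folded_jsfs(ds$geno, "SPA", "IRQ")
  expect_identical(dim(js2$matrix), c(31L, 11L))
})

test_that("14-bin reduction conserves totals and concentrates as expected", {
  ds <- tiny_gws_dataset()
  js <- folded_jsfs(ds$geno, "EURw", "EURns")
  b <- bin_jsfs_14(js)
  expect_identical(nrow(b), 14L)
  expect_equal(sum(b$count), js$n_sites)
  # all-doubleton-in-A case lands in the (interior, 0) bin
  H <- matrix(rep(c(1, 1, 0, 0, 0, 0, 0, 0), 5), nrow = 8)
  jd <- folded_jsfs(H, "A", "B", pop = rep(c("A", "B"), each = 4))
  bd <- bin_jsfs_14(jd)
  expect_equal(bd$count[bd$bin_A == "interior" & bd$bin_B == "0"], 5)
  expect_equal(sum(bd$count), 5)
  # uniform folded matrix aggregates to the cell-group sizes
  js$matrix[] <- 1
  js$matrix[1, 1] <- 0
  js$matrix[31, 31] <- 0
  bu <- bin_jsfs_14(js)
  expect_equal(sum(bu$count), 31 * 31 - 2)
  expect_equal(bu$count[bu$bin_A == "singleton" & bu$bin_B == "singleton"],
               1)
  expect_equal(bu$count[bu$bin_A == "interior" & bu$bin_B == "interior"],
               28 * 28)
  expect_error(bin_jsfs_14(folded_jsfs(matrix(0L, 3, 2), "A", "B",
                                       pop = c("A", "B", "B"))),
               "at least 2")
})

test_that("expected spectra are probability distributions", {
  m <- two_pop_model(split_years = 5.79e5, m = 0, n_dip = c(3, 3))
  p <- expected_jsfs(m, c("A", "B"), n_sim_loci = 800, seed = 2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_identical(unclass(p)[1, 1], 0)
})

test_that("long-isolated populations share no expected polymorphism", {
  m <- two_pop_model(ne = 1e4, split_years = 5.79e6, m = 0,
                     n_dip = c(3, 3))
  p <- unclass(expected_jsfs(m, c("A", "B"), 1500, seed = 3, p_floor = 0))
  private <- sum(p[, 1]) + sum(p[1, ])
  expect_gt(private, 0.95)
})

test_that("a panmictic pair reproduces the folded Watterson spectrum", {
  # two labels on one effectively unstructured population
  m <- two_pop_model(ne = 2e4, split_years = 1, m = 0, n_dip = c(5, 5))
  es <- crowdemog:::compile_model(m)
  raw <- crowdemog:::cpp_sim_jsfs(es, 6000L, 2000, 3.18e-9,
                                  rbind(c(0L, 1L)), 17, FALSE)[[1]]
  n <- 20
  pooled <- vapply(1:(n - 1), function(k) {
    i <- pmax(0, k - 10):pmin(10, k)
    sum(raw[cbind(i + 1, k - i + 1)])
  }, numeric(1))
  pooled <- pooled / sum(pooled)
  watterson <- (1 / 1:(n - 1)) / sum(1 / 1:(n - 1))
  expect_lt(max(abs(pooled - watterson)), 0.01)
})

test_that("the composite log-likelihood follows the multinomial formula", {
  expect_equal(composite_loglik(c(3, 1), c(0.75, 0.25)),
               (3 * log(0.75) + log(0.25)) / log(10))
  expect_equal(composite_loglik(c(3, 1), c(0.75, 0.25)), -0.9768,
               tolerance = 1e-4)
  expect_identical(composite_loglik(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0)
  expect_equal(composite_loglik(rep(2, 5), rep(0.2, 5)), 10 * log10(0.2))
  expect_error(composite_loglik(c(1, 1), c(1, 0)), "zero")
  expect_error(composite_loglik(c(1, 1, 1), c(0.5, 0.5)), "shapes")
})

test_that("AIC uses the fastsimcoal convention on log10 likelihoods", {
  expect_identical(aic(0, 0), 0)
  expect_equal(aic(-10, 2), 4 + 2 * log(10) * 10)
  expect_equal(aic(-10, 2), 50.052, tolerance = 1e-4)
  expect_error(aic(0, -1), "k")
  f1 <- crowdemog:::new_demog_fit("gws", list(), -10, 2, tibble::tibble())
  f2 <- crowdemog:::new_demog_fit("lsi", list(), -12, 2, tibble::tibble())
  expect_identical(attr(compare_models(f1, f2), "winner"), "gws")
})

test_that("neutral-genome scaling reproduces the published arithmetic", {
  expect_identical(neutral_genome_scaling(5774276, 11146221, 625134484),
                   329623861)
  expect_identical(neutral_genome_scaling(10, 10, 90), 100)
  expect_identical(neutral_genome_scaling(1, 2, 2), 2)
  expect_error(neutral_genome_scaling(3, 2, 2), "exceed")
  expect_error(neutral_genome_scaling(0, 2, 2), "> 0")
})

test_that("the bootstrap locus count covers the scaled neutral genome", {
  expect_identical(bootstrap_locus_count(11146221, 625134484, 1000),
                   636281)
  expect_identical(bootstrap_locus_count(10, 85, 10), 10)
})

test_that("joint spectra round-trip through the .obs dialect", {
  ds <- tiny_gws_dataset()
  js <- folded_jsfs(ds$geno, "EURns", "IRQ")
  path <- withr::local_tempfile(fileext = ".obs")
  write_jsfs_obs(js, path)
  expect_identical(readLines(path, n = 1), "1 observations")
  js2 <- read_jsfs_obs(path)
  expect_equal(unclass(js2$matrix), unclass(js$matrix))
  expect_equal(js2$pops, js$pops)
  expect_equal(js2$n_sites, js$n_sites)
})

test_that("projection and complete-case handling of missing data behave", {
  ds <- tiny_gws_dataset()
  full <- folded_jsfs(ds$geno, "SPA", "IRQ")
  # complete data: projecting to the full sizes reproduces complete-case
  proj <- folded_jsfs(ds$geno, "SPA", "IRQ", mode = "projection",
                      project = c(30, 10))
  expect_equal(unclass(proj$matrix), unclass(full$matrix),
               tolerance = 1e-9)
  sp <- spike_missingness(tiny_gws_dataset(seed = 31), 0.1, seed = 2)
  cc <- folded_jsfs(sp$geno, "SPA", "IRQ")
  expect_gt(cc$n_skipped, 0)
  expect_lt(cc$n_sites, folded_jsfs(tiny_gws_dataset(seed = 31)$geno,
                                    "SPA", "IRQ")$n_sites)
  # projection keeps more sites than complete-case under missingness
  pj <- folded_jsfs(sp$geno, "SPA", "IRQ", mode = "projection",
                    project = c(24, 8))
  expect_gt(pj$n_sites, cc$n_sites)
})

test_that("joint spectra round-trip through the self-describing TSV", {
  ds <- tiny_gws_dataset()
  js <- folded_jsfs(ds$geno, "SPA", "EURns")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_jsfs_tsv(js, path)
  js2 <- read_jsfs_tsv(path)
  expect_equal(unclass(js2$matrix), unclass(js$matrix))
  expect_equal(js2$pops, js$pops)
})
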