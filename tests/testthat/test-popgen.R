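test_that("windowed pi, dxy and Hudson FST match first-principles values", {
  # two haplotypes differing at 1 of 100 accessible sites: pi = 0.01
  H <- matrix(c(0, 1), nrow = 2, ncol = 1)
  g <- make_geno(H, pop = c("A", "A"), pos = 50, contig_len = 100)
  ws <- window_stats(g, window_size = 100)
  expect_equal(ws$value[ws$stat == "pi" & ws$pop_a == "A"], 0.01)

  # fixed differences at every site: FST = 1, dxy = 1
  Hf <- rbind(matrix(0, 4, 5), matrix(1, 4, 5))
  gf <- make_geno(Hf, pop = rep(c("A", "B"), each = 4), pos = 1:5,
                  contig_len = 5)
  wf <- window_stats(gf, window_size = 5)
  expect_equal(wf$value[wf$stat == "fst"], 1)
  expect_equal(wf$value[wf$stat == "dxy"], 1)
  expect_equal(wf$value[wf$stat == "pi"], c(0, 0))

  # identical allele frequencies: expected numerator 0, estimate near 0
  set.seed(2)
  block <- matrix(rbinom(30 * 40, 1, 0.5), nrow = 30)
  gi <- make_geno(rbind(block, block), pop = rep(c("A", "B"), each = 30),
                  pos = 1:40, contig_len = 40)
  wi <- window_stats(gi, window_size = 40)
  expect_lt(abs(wi$value[wi$stat == "fst"]), 0.05)
})

test_that("windows with no accessible sites are flagged missing, not zero", {
  H <- matrix(c(0, 1), nrow = 2, ncol = 1)
  g <- make_geno(H, pop = c("A", "A"), pos = 10, contig_len = 200)
  mask <- tibble::tibble(contig = "c1", start = 1, end = 100)
  ws <- window_stats(g, window_size = 100, mask = mask)
  first <- ws[ws$start == 1 & ws$stat == "pi", ]
  second <- ws[ws$start == 101 & ws$stat == "pi", ]
  expect_equal(first$value, 0.01)
  expect_true(is.na(second$value))
  expect_identical(second$n_accessible, 0)
})

test_that("net divergence identity holds exactly in every emitted window", {
  ds <- tiny_gws_dataset()
  ws <- window_stats(ds$geno, window_size = 20000)
  wide <- tidyr::pivot_wider(ws, names_from = "stat",
                             values_from = "value")
  pis <- ws[ws$stat == "pi", ]
  for (r in which(!is.na(wide$da))) {
    w <- wide[r, ]
    px <- pis$value[pis$start == w$start & pis$contig == w$contig &
                      pis$pop_a == w$pop_a]
    py <- pis$value[pis$start == w$start & pis$contig == w$contig &
                      pis$pop_a == w$pop_b]
    expect_identical(w$da, w$dxy - (px + py) / 2)
  }
  expect_equal(net_divergence(0.004, 0.003, 0.003), 0.001)
  expect_equal(net_divergence(0.003, 0.003, 0.003), 0)
  expect_equal(net_divergence(0.002, 0.003, 0.003), -0.001)
})

test_that("windowed statistics ignore sample order within populations", {
  ds <- tiny_gws_dataset()
  g <- ds$geno
  perm <- g
  for (p in unique(g$pop)) {
    rows <- which(g$pop == p)
    set.seed(match(p, unique(g$pop)))
    perm$haplotypes[rows, ] <- g$haplotypes[sample(rows), ]
  }
  expect_equal(window_stats(perm, 50000), window_stats(g, 50000))
})

test_that("net divergence converts to absolute time", {
  cfg <- global_config()
  expect_equal(da_to_years(2 * cfg$mutation_rate, cfg), 5.79)
  expect_equal(da_to_years(0.001, cfg), 910377.4, tolerance = 1e-6)
  expect_equal(da_to_years(3.767e-4, cfg), 343000, tolerance = 2e-3)
  expect_true(is.na(da_to_years(0, cfg)))
  expect_true(is.na(da_to_years(-0.001, cfg)))
})

test_that("Patterson's D matches direct arithmetic and the pattern-count oracle", {
  expect_equal(patterson_d(0, 1, 1, 0)$D, 1)
  expect_equal(patterson_d(c(0, 1), c(1, 0), c(1, 1), c(0, 0))$D, 0)
  r <- patterson_d(0.2, 0.8, 0.6, 0)
  expect_equal(r$abba, 0.384)
  expect_equal(r$baba, 0.024)
  expect_equal(r$D, 0.882, tolerance = 1e-3)
  set.seed(9)
  for (rep in 1:20) {
    S <- sample(20:100, 1)
    g1 <- rbinom(S, 1, 0.4); g2 <- rbinom(S, 1, 0.6)
    g3 <- rbinom(S, 1, 0.5); gO <- rep(0, S)
    expect_equal(patterson_d(g1, g2, g3, gO)$D,
                 brute_patterson_d(g1, g2, g3, gO))
  }
  # zero denominator is flagged, not fabricated
  expect_true(is.na(patterson_d(c(1, 0), c(1, 0), c(0, 0), c(0, 0))$D))
})

test_that("f4-ratio brackets the admixture fraction", {
  ds <- tiny_gws_dataset()
  fr <- derived_freqs(ds$geno)
  zero <- rep(0, nrow(fr))
  blk <- fr$contig
  # clone of the donor: alpha = 1
  r1 <- f4_ratio(fr$IRQ, zero, fr$EURns, fr$EURns, fr$SPA, block = blk)
  expect_equal(r1$alpha, 1)
  # swamped EURw carries a large hooded-crow fraction
  r <- f4_ratio(fr$IRQ, zero, fr$EURw, fr$EURns, fr$SPA, block = blk)
  expect_gt(r$alpha, 0.3)
  expect_lt(r$alpha, 1)
  # strict isolation: alpha compatible with 0
  dsi <- generate_dataset("gws",
    params = list(m_spa_eurw = 0, m_eurw_spa = 0, m_irq_eurns = 0,
                  m_eurns_irq = 0, m_eurns_eurw = 0, m_eurw_eurns = 0),
    layout = list(n_contigs = 6, loci_per_contig = 30,
                  locus_length = 2000, barrier_contig = 6,
                  barrier_loci = 0), seed = 12)
  f0 <- derived_freqs(dsi$geno)
  r0 <- f4_ratio(f0$IRQ, rep(0, nrow(f0)), f0$EURw, f0$EURns, f0$SPA,
                 block = f0$contig)
  expect_lt(abs(r0$alpha), 2 * r0$se)
})

test_that("windowed f_dM detects the direction and the barrier deficit", {
  ds <- tiny_gws_dataset(seed = 7, barrier_loci = 12)
  fd <- fdm_windows(ds$geno, "SPA", "EURw", "EURns", window_snps = 50)
  expect_true(all(fd$n_snps <= 50))
  expect_gt(mean(fd$fdm, na.rm = TRUE), 0)  # EURw<->EURns flow
  bar <- fd$contig == ds$truth$barrier$contig
  expect_lt(mean(fd$fdm[bar], na.rm = TRUE),
            mean(fd$fdm[!bar], na.rm = TRUE))
  # no gene flow: mean compatible with zero
  dsi <- generate_dataset("gws",
    params = list(m_spa_eurw = 0, m_eurw_spa = 0, m_irq_eurns = 0,
                  m_eurns_irq = 0, m_eurns_eurw = 0, m_eurw_eurns = 0),
    layout = list(n_contigs = 6, loci_per_contig = 30,
                  locus_length = 2000, barrier_contig = 6,
                  barrier_loci = 0), seed = 13)
  f0 <- fdm_windows(dsi$geno, "SPA", "EURw", "EURns", 50)
  se <- sd(f0$fdm, na.rm = TRUE) / sqrt(sum(!is.na(f0$fdm)))
  expect_lt(abs(mean(f0$fdm, na.rm = TRUE)), 2 * se)
})

test_that("introgression-length correlation behaves on toy inputs", {
  lens <- tibble::tibble(contig = paste0("c", 1:6),
                         length = c(10, 20, 30, 40, 50, 60) * 1e6)
  up <- tibble::tibble(contig = lens$contig, fdm = lens$length / 1e8)
  expect_equal(length_vs_introgression(up, lens)$r, 1)
  dn <- tibble::tibble(contig = lens$contig, fdm = rev(lens$length) / 1e8)
  expect_lt(length_vs_introgression(dn, lens)$r, 0)
  flat <- tibble::tibble(contig = lens$contig, fdm = rep(0.1, 6))
  expect_true(is.na(length_vs_introgression(flat, lens)$r))
  # permutation null is centred on zero
  set.seed(4)
  rs <- replicate(200, {
    p <- tibble::tibble(contig = lens$contig, fdm = sample(up$fdm))
    length_vs_introgression(p, lens)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("the four-gamete fraction flags recombination and only recombination", {
  H <- matrix(c(0, 0, 1, 1,
                0, 1, 0, 1), ncol = 2)
  expect_equal(four_gamete_fraction(H), 1)
  # single non-recombining infinite-sites locus: violations impossible
  m <- one_pop_model(ne = 1e5, n_dip = 8)
  es <- crowdemog:::compile_model(m)
  loci <- crowdemog:::cpp_sim_snp_loci(es, 40L, 10000, 3.18e-9, 17)
  fr <- vapply(loci, function(l) {
    if (ncol(l$geno) < 2) return(NA_real_)
    four_gamete_fraction(l$geno)
  }, numeric(1))
  expect_true(all(fr[!is.na(fr)] == 0))
  expect_true(is.na(four_gamete_fraction(matrix(c(0, 1), 2, 1))))
})

test_that("four-gamete violations increase with the recombination rate", {
  # oracle: msprime with recombination; the package engine is
  # recombination-free by design, so the oracle provides the rho > 0 loci
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, msprime",
    "rho_rates = [0.0, 2.5e-8, 2.5e-7]",
    "out = []",
    "for i, r in enumerate(rho_rates):",
    "    viol = tot = 0",
    "    reps = msprime.sim_ancestry(samples=10, population_size=10000,",
    "        sequence_length=10000, recombination_rate=r, ploidy=2,",
    "        num_replicates=30, random_seed=7 + i)",
    "    for ts in reps:",
    "        mts = msprime.sim_mutations(ts, rate=5e-8, random_seed=11,",
    "            discrete_genome=False)",
    "        G = mts.genotype_matrix()",
    "        S = G.shape[0]",
    "        for a in range(S):",
    "            for b in range(a + 1, S):",
    "                ga, gb = G[a] > 0, G[b] > 0",
    "                tot += 1",
    "                h = {(x, y) for x, y in zip(ga, gb)}",
    "                viol += len(h) == 4",
    "    out.append(viol / tot)",
    "print('\\t'.join(str(x) for x in out))"), script)
  res <- system2("python", script, stdout = TRUE)
  fr <- as.numeric(strsplit(res[length(res)], "\t")[[1]])
  expect_identical(fr[1], 0)
  expect_lt(fr[1], fr[2])
  expect_lt(fr[2], fr[3])
})

test_that("the exact HWE test matches hand-computed probabilities", {
  # 1 AA + 1 aa: het counts {0, 2} with probabilities {1/3, 2/3}
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_p(0, 2, 0), 1)
  # 100 individuals all heterozygous: far out of equilibrium
  expect_lt(hwe_exact_p(0, 100, 0), 1e-10)
  # counts at HWE proportions are retained comfortably
  expect_gt(hwe_exact_p(25, 50, 25), 0.05)
  expect_equal(hwe_exact_p(0, 0, 0), 1)
})

test_that("HWE filtering removes failing sites except on the barrier contig", {
  # 100 diploids: site 1 all-heterozygous (extreme excess), site 2 at
  # Hardy-Weinberg proportions
  set.seed(8)
  het <- rep(c(0L, 1L), 100)
  hw <- as.integer(rbinom(200, 1, 0.5))
  g <- make_geno(cbind(het, hw), pop = rep("A", 200), pos = c(1L, 2L),
                 contig_len = 10)
  res <- hwe_filter(g, alpha = 1e-4)
  expect_false(1L %in% res$retained)
  expect_true(1L %in% res$removed$site)
  expect_true(2L %in% res$retained)
  # the same extreme site on the exempt barrier contig is retained
  res2 <- hwe_filter(g, alpha = 1e-4, barrier_contig = "c1")
  expect_true(1L %in% res2$retained)
  expect_identical(nrow(res2$removed), 0L)
})

test_that("Tajima's D matches a hand computation and the growth signature", {
  # n = 4 sequences, S = 3 segregating sites
  H <- matrix(c(1, 0, 0, 0,
                1, 1, 0, 0,
                0, 1, 1, 0), nrow = 4)
  n <- 4; S <- 3
  # independent arithmetic: mean pairwise differences over the 6 pairs
  pd <- combn(4, 2, function(ij) sum(H[ij[1], ] != H[ij[2], ]))
  k <- mean(pd)
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_hand <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(H), D_hand)
  expect_true(is.na(tajimas_d(matrix(0, 4, 5))))  # no segregating sites

  # neutral equilibrium: mean D near 0; strong growth: clearly negative
  m0 <- one_pop_model(ne = 2e4, n_dip = 10)
  es0 <- crowdemog:::compile_model(m0)
  loci <- crowdemog:::cpp_sim_snp_loci(es0, 1000L, 2000, 3.18e-9, 9)
  d0 <- vapply(loci, function(l)
    if (ncol(l$geno) > 1) tajimas_d(l$geno) else NA_real_, numeric(1))
  expect_lt(abs(mean(d0, na.rm = TRUE)), 0.1)
  mg <- one_pop_model(ne = 2e5, n_dip = 10, growth_rate = 1e-3,
                      growth_start_time = 3e4)
  esg <- crowdemog:::compile_model(mg)
  lg <- crowdemog:::cpp_sim_snp_loci(esg, 400L, 2000, 3.18e-9, 9)
  dg <- vapply(lg, function(l)
    if (ncol(l$geno) > 1) tajimas_d(l$geno) else NA_real_, numeric(1))
  expect_lt(mean(dg, na.rm = TRUE), -0.5)
})
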