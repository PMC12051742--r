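# Shared fixtures and independent brute-force oracles used across tests.

# A small GWS synthetic dataset (memoised per seed within a test run).
.tiny_cache <- new.env(parent = emptyenv())
tiny_gws_dataset <- function(seed = 11, barrier_loci = 10) {
  key <- paste0("d", seed, "_", barrier_loci)
  if (!is.null(.tiny_cache[[key]])) return(.tiny_cache[[key]])
  ds <- generate_dataset(
    "gws",
    layout = list(n_contigs = 6, loci_per_contig = 40,
                  locus_length = 2000, barrier_contig = 6,
                  barrier_loci = barrier_loci),
    seed = seed)
  .tiny_cache[[key]] <- ds
  ds
}

# independent brute-force fold: enumerate every site, fold by first
# principles (minor-total rule, ties to the smaller first index)
brute_fold_jsfs <- function(iA, iB, nA, nB) {
  out <- matrix(0, nA + 1, nB + 1)
  for (k in seq_along(iA)) {
    i <- iA[k]; j <- iB[k]
    ci <- nA - i; cj <- nB - j
    take <- if (i + j < ci + cj) c(i, j)
            else if (i + j > ci + cj) c(ci, cj)
            else if (i < ci) c(i, j)
            else if (i > ci) c(ci, cj)
            else if (j <= cj) c(i, j) else c(ci, cj)
    out[take[1] + 1, take[2] + 1] <- out[take[1] + 1, take[2] + 1] + 1
  }
  out[1, 1] <- 0
  out[nA + 1, nB + 1] <- 0
  out
}

# independent pattern-count ABBA-BABA for fixed (0/1) site patterns
brute_patterson_d <- function(g1, g2, g3, gO) {
  abba <- sum(g1 == 0 & g2 == 1 & g3 == 1 & gO == 0)
  baba <- sum(g1 == 1 & g2 == 0 & g3 == 1 & gO == 0)
  if (abba + baba == 0) return(NA_real_)
  (abba - baba) / (abba + baba)
}

# assemble a pop_genotypes object from raw pieces
make_geno <- function(haplotypes, pop, pos = NULL, contig = "c1",
                      contig_len = NULL, outgroup = NULL) {
  S <- ncol(haplotypes)
  if (is.null(pos)) pos <- seq_len(S)
  if (is.null(contig_len)) contig_len <- max(pos)
  samples <- paste0(pop[seq(1, length(pop), 2)], "_",
                    seq_len(length(pop) / 2))
  structure(list(
    sites = tibble::tibble(contig = rep(contig, S), pos = pos,
                           ref = rep("A", S), alt = rep("G", S)),
    haplotypes = haplotypes, pop = pop, samples = samples,
    contigs = tibble::tibble(contig = contig, length = contig_len),
    outgroup = outgroup), class = "pop_genotypes")
}

two_pop_model <- function(ne = 1e4, split_years = 5790 * 10, m = 0,
                          n_dip = c(2, 2)) {
  mg <- if (m > 0)
    tibble::tibble(start_time = 0, end_time = split_years,
                   donor = c("A", "B"), recipient = c("B", "A"), rate = m)
  else empty_migration()
  demographic_model(
    "two",
    dplyr::bind_rows(population("A", n_dip[1], ne),
                     population("B", n_dip[2], ne),
                     population("ANC", 0, ne)),
    splits = tibble::tibble(time = c(split_years, split_years),
                            derived_pop = c("A", "B"),
                            ancestral_pop = c("ANC", "ANC")),
    migration = mg)
}

one_pop_model <- function(ne = 1e4, n_dip = 5, growth_rate = 0,
                          growth_start_time = 0) {
  demographic_model("one", population("A", n_dip, ne, growth_rate,
                                      growth_start_time))
}

# GWS panel pairs in canonical order
crow_pairs <- function() sfs_panel_pairs(c("SPA", "EURw", "EURns", "IRQ"))
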