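# Synthetic whole-dataset generator: VCF + population map + outgroup table
# + truth record, with a chr18-like migration-resistant barrier region.

default_layout <- function() {
  list(n_contigs = 20L, loci_per_contig = 50L, locus_length = 2000L,
       barrier_contig = 18L, barrier_loci = 40L)
}

#' Generate a complete synthetic dataset
#'
#' Simulates independent non-recombining neutral loci tiled into synthetic
#' contigs under the chosen scenario.  Loci inside the barrier span are
#' simulated under the same demography with the EURw<->EURns and SPA<->EURw
#' migration set to zero, emulating the effect of divergent selection on
#' effective migration at the plumage locus.  Biallelic SNPs are written as
#' VCF 4.2 (ancestral allele as REF), together with a sample-to-population
#' map, a haploid outgroup allele table, and a truth record sufficient to
#' regenerate the dataset byte-identically.
#'
#' @param scenario `"gws"` or `"lsi"`.
#' @param params Named list of scenario parameters (defaults: the
#'   fastsimcoal point estimates; see [build_gws_model()]).
#' @param layout List with `n_contigs`, `loci_per_contig`, `locus_length`,
#'   `barrier_contig`, `barrier_loci` (defaults 20 x 50 x 2000 bp with a
#'   40-locus barrier on contig 18).
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @return A `synthetic_dataset`: file paths (`vcf`, `pop_map_file`,
#'   `outgroup_file`, `truth_file`), tibbles (`pop_map`, `contigs`,
#'   `outgroup`), the `truth` record, and the in-memory `geno`
#'   (`pop_genotypes`).
#' @export
generate_dataset <- function(scenario = c("gws", "lsi"), params = list(),
                             layout = list(), seed = 1L,
                             dir = tempfile("crowdemog_data_")) {
  scenario <- match.arg(scenario)
  lay <- utils::modifyList(default_layout(), layout)
  if (lay$barrier_contig > lay$n_contigs)
    stop("layout error: barrier contig ", lay$barrier_contig,
         " exceeds the ", lay$n_contigs, "-contig layout", call. = FALSE)
  if (lay$barrier_loci > lay$loci_per_contig)
    stop("layout error: barrier span exceeds its contig", call. = FALSE)
  builder <- scenario_builder(scenario)
  model <- attach_outgroup(builder(params))
  barrier_model <- zero_barrier_migration(model)
  es <- compile_model(model)
  es_b <- compile_model(barrier_model)

  n_total <- lay$n_contigs * lay$loci_per_contig
  loci <- tibble::tibble(
    locus = seq_len(n_total),
    contig = rep(seq_len(lay$n_contigs), each = lay$loci_per_contig),
    within = rep(seq_len(lay$loci_per_contig), lay$n_contigs))
  b_first <- (lay$loci_per_contig - lay$barrier_loci) %/% 2L + 1L
  loci$barrier <- loci$contig == lay$barrier_contig &
    loci$within >= b_first & loci$within < b_first + lay$barrier_loci

  seed_neutral <- as.double(seed)
  seed_barrier <- as.double(seed) + 777777
  L <- lay$locus_length
  sims_n <- cpp_sim_snp_loci(es, sum(!loci$barrier), L, es$mutation_rate,
                             seed_neutral)
  sims_b <- if (any(loci$barrier))
    cpp_sim_snp_loci(es_b, sum(loci$barrier), L, es$mutation_rate,
                     seed_barrier) else list()
  sims <- vector("list", n_total)
  sims[which(!loci$barrier)] <- sims_n
  sims[which(loci$barrier)] <- sims_b

  n_og <- 2L  # outgroup haplotypes (last rows of the simulated matrices)
  n_in <- sum(es$samples) - n_og
  site_list <- list()
  hap_list <- list()
  og_list <- list()
  for (k in seq_len(n_total)) {
    s <- sims[[k]]
    if (length(s$positions) == 0) next
    gin <- s$geno[seq_len(n_in), , drop = FALSE]
    ac <- colSums(gin)
    keep <- ac > 0 & ac < n_in  # polymorphic within the sampled ingroup
    if (!any(keep)) next
    site_list[[length(site_list) + 1]] <- tibble::tibble(
      contig = paste0("contig", loci$contig[k]),
      pos = (loci$within[k] - 1L) * L + s$positions[keep])
    hap_list[[length(hap_list) + 1]] <- gin[, keep, drop = FALSE]
    og_list[[length(og_list) + 1]] <- s$geno[n_in + 1L, keep]
  }
  sites <- dplyr::bind_rows(site_list)
  H <- do.call(cbind, hap_list)
  og <- unlist(og_list)

  # seeded REF/ALT base assignment (REF is the ancestral allele 0)
  set.seed(as.integer((seed + 104729) %% .Machine$integer.max))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(sites), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  sites$ref <- ref
  sites$alt <- unname(alt)

  pops <- es$pop_names[es$samples > 0]
  pops <- setdiff(pops, "OUT")
  dip <- es$samples[match(pops, es$pop_names)] / 2
  sample_names <- unlist(lapply(seq_along(pops), function(p)
    paste0(pops[p], "_", seq_len(dip[p]))))
  pop_map <- tibble::tibble(sample = sample_names,
                            population = rep(pops, dip))
  contigs <- tibble::tibble(contig = paste0("contig",
                                            seq_len(lay$n_contigs)),
                            length = as.integer(lay$loci_per_contig * L))
  outgroup <- tibble::tibble(contig = sites$contig, pos = sites$pos,
                             allele = og)
  barrier_coords <- list(
    contig = paste0("contig", lay$barrier_contig),
    start = (b_first - 1L) * L + 1L,
    end = (b_first - 1L + lay$barrier_loci) * L)
  truth <- list(scenario = scenario,
                params = utils::modifyList(
                  if (scenario == "gws") default_gws_params()
                  else default_lsi_params(), params),
                layout = lay, seed = as.integer(seed),
                seed_neutral = seed_neutral, seed_barrier = seed_barrier,
                barrier = barrier_coords)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "dataset.vcf"),
                pop_map_file = file.path(dir, "pop_map.tsv"),
                outgroup_file = file.path(dir, "outgroup.tsv"),
                truth_file = file.path(dir, "truth.json"))
  write_vcf(sites, H, sample_names, contigs, paths$vcf)
  utils::write.table(pop_map, paths$pop_map_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(outgroup, paths$outgroup_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, paths$truth_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  geno <- structure(list(sites = sites, haplotypes = H,
                         pop = rep(pops, 2 * dip), samples = sample_names,
                         contigs = contigs, outgroup = og),
                    class = "pop_genotypes")
  structure(c(paths, list(pop_map = pop_map, contigs = contigs,
                          outgroup = outgroup, truth = truth, geno = geno,
                          dir = dir)),
            class = "synthetic_dataset")
}

# remove the migration edges that divergent selection suppresses at the
# barrier locus: all gene flow touching EURw<->EURns and SPA<->EURw
zero_barrier_migration <- function(model) {
  mg <- model$migration
  blocked <- (mg$donor == "EURw" & mg$recipient == "EURns") |
             (mg$donor == "EURns" & mg$recipient == "EURw") |
             (mg$donor == "SPA" & mg$recipient == "EURw") |
             (mg$donor == "EURw" & mg$recipient == "SPA")
  m2 <- demographic_model(paste0(model$name, "_barrier"),
                          model$populations, model$splits,
                          mg[!blocked, ], model$config)
  attr(m2, "scenario") <- attr(model, "scenario")
  m2
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> scenario ", x$truth$scenario, ": ",
      nrow(x$geno$sites), " SNPs, ", length(x$geno$samples),
      " samples, ", nrow(x$contigs), " contigs (barrier on ",
      x$truth$barrier$contig, ")\n  dir: ", x$dir, "\n", sep = "")
  invisible(x)
}

#' Spike missing genotype calls into a dataset
#'
#' Sets diploid genotype calls to missing independently at the given rate
#' and rewrites the VCF; the truth record is updated.
#'
#' @param dataset A `synthetic_dataset`.
#' @param rate Missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return The modified `synthetic_dataset`.
#' @export
spike_missingness <- function(dataset, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(dataset)
  g <- dataset$geno
  ns <- length(g$samples)
  set.seed(as.integer(seed %% .Machine$integer.max))
  drop <- matrix(runif(ns * nrow(g$sites)) < rate, ns)
  H <- g$haplotypes
  for (s in seq_len(ns)) {
    H[2 * s - 1, drop[s, ]] <- NA
    H[2 * s, drop[s, ]] <- NA
  }
  g$haplotypes <- H
  dataset$geno <- g
  dataset$truth$missingness <- list(rate = rate, seed = as.integer(seed))
  write_vcf(g$sites, H, g$samples, dataset$contigs, dataset$vcf)
  jsonlite::write_json(dataset$truth, dataset$truth_file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dataset
}

#' Regenerate a dataset from its truth record
#'
#' @param truth A truth record (list) or path to a truth JSON.
#' @param dir Output directory.
#' @return A `synthetic_dataset` byte-identical to the original (before any
#'   missingness spiking).
#' @export
regenerate_dataset <- function(truth, dir = tempfile("crowdemog_regen_")) {
  if (is.character(truth)) truth <- jsonlite::read_json(truth,
                                                        simplifyVector = TRUE)
  generate_dataset(truth$scenario, truth$params, truth$layout,
                   truth$seed, dir)
}
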