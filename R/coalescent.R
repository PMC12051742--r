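# User-facing simulation layer over the C++ structured-coalescent core.

# leaf labels POP_ind_hap, diploid individuals = consecutive haplotype pairs
leaf_labels <- function(pop_names, samples) {
  unlist(lapply(seq_along(samples), function(p) {
    n <- samples[p]
    if (n == 0) return(character())
    ind <- (seq_len(n) + 1L) %/% 2L
    hap <- rep(c("a", "b"), length.out = n)
    paste0(pop_names[p], "_", ind, "_", hap)
  }))
}

# Convert a (parent, time) genealogy to an ape "phylo" with branch lengths
# in generations.  Leaves are nodes 0..n-1 (0-based), internals follow in
# coalescence-time order, the root last.
genealogy_to_phylo <- function(parent, time, n_leaves, tip_labels) {
  nn <- length(parent)
  stopifnot(nn == 2 * n_leaves - 1)
  kids <- vector("list", nn)
  root <- which(parent == -1L)
  for (v in seq_len(nn)) {
    p <- parent[v] + 1L
    if (p > 0L) kids[[p]] <- c(kids[[p]], v)
  }
  # ape convention: tips 1..n, internals n+1..2n-1 numbered in preorder
  # (root = n+1), edges listed cladewise
  map <- integer(nn)
  map[seq_len(n_leaves)] <- seq_len(n_leaves)
  edge <- matrix(0L, nn - 1L, 2L)
  elen <- numeric(nn - 1L)
  k <- 0L
  nin <- 0L
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > n_leaves) {
      nin <- nin + 1L
      map[v] <- n_leaves + nin
    }
    pv <- parent[v] + 1L
    if (pv > 0L) {
      k <- k + 1L
      edge[k, ] <- c(map[pv], map[v])
      elen[k] <- time[pv] - time[v]
    }
    for (ch in rev(kids[[v]])) stack <- c(stack, ch)
  }
  structure(list(edge = edge, edge.length = elen,
                 tip.label = tip_labels, Nnode = n_leaves - 1L),
            class = "phylo", order = "cladewise")
}

# Inverse mapping used by the topology-weighting backend: phylo -> 0-based
# parent array with node ids tips first.
phylo_to_parent <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- rep(-1L, nn)
  for (k in seq_len(nrow(tree$edge)))
    parent[tree$edge[k, 2]] <- tree$edge[k, 1] - 1L
  parent
}

new_haplotype_block <- function(locus_id, locus_length, positions,
                                haplotypes, alleles = c("binary", "acgt"),
                                ancestral = NULL) {
  alleles <- match.arg(alleles)
  structure(list(locus_id = locus_id, locus_length = locus_length,
                 positions = positions, haplotypes = haplotypes,
                 alleles = alleles, ancestral = ancestral),
            class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("<haplotype_block> ", x$locus_id, ": ", nrow(x$haplotypes),
      " haplotypes x ", length(x$positions), " segregating sites (",
      x$alleles, ", ", x$locus_length, " bp)\n", sep = "")
  invisible(x)
}

#' Simulate one non-recombining locus
#'
#' Draws a genealogy from the structured coalescent under the model's sizes,
#' growth, splits and migration, then drops mutations along the branches.
#'
#' @param model A `demographic_model`.
#' @param locus_length Locus length in bp.
#' @param mutation_model `"infinite_sites"` (0/1 alleles, every site hit
#'   once) or `"hky"` (A/C/G/T, recurrent hits allowed, transitions with
#'   probability `ts_fraction`).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param samples Optional named vector of haploid sample counts overriding
#'   the model's diploid sample sizes.
#' @param ts_fraction Probability that a finite-sites mutation is a
#'   transition (default 0.5, i.e. transition/transversion ratio 2 on a
#'   per-type basis).
#' @return A list with elements `tree` (an [ape::phylo] with branch lengths
#'   in generations) and `block` (a `haplotype_block`).
#' @export
simulate_locus <- function(model, locus_length, mutation_model =
                             c("infinite_sites", "hky"), seed,
                           samples = NULL, ts_fraction = 0.5) {
  mutation_model <- match.arg(mutation_model)
  if (locus_length < 1) stop("`locus_length` must be >= 1", call. = FALSE)
  es <- compile_model(model, samples)
  gl <- cpp_sim_genealogies(es, 1L, as.double(seed))[[1]]
  labs <- leaf_labels(es$pop_names, es$samples)
  tree <- genealogy_to_phylo(gl$parent, gl$time, gl$n_leaves, labs)
  if (mutation_model == "infinite_sites") {
    loc <- cpp_sim_snp_loci(es, 1L, locus_length, es$mutation_rate,
                            as.double(seed))[[1]]
    haps <- loc$geno
    rownames(haps) <- labs
    block <- new_haplotype_block("locus_1", locus_length, loc$positions,
                                 haps, "binary",
                                 ancestral = rep(0L, length(loc$positions)))
  } else {
    block <- mutate_finite_sites(tree, locus_length,
                                 ts_fraction = ts_fraction,
                                 mu = es$mutation_rate, seed = seed)
  }
  list(tree = tree, block = block)
}

#' Drop finite-sites (HKY) mutations on a genealogy
#'
#' Sites are drawn uniformly along the locus allowing recurrent hits; each
#' mutation is a transition with probability `ts_fraction`, otherwise one of
#' the two transversions equiprobably; base frequencies are equal.
#'
#' @param tree An [ape::phylo] with branch lengths in generations.
#' @param locus_length Locus length in bp.
#' @param ts_fraction Transition probability per mutation, in `[0, 1]`.
#' @param mu Per-site per-generation mutation rate.
#' @param seed Integer seed.
#' @return A `haplotype_block` with A/C/G/T alleles at the polymorphic
#'   sites; attributes `n_mutations` and `n_transitions` report the realised
#'   mutation process (including hits that left no polymorphism).
#' @export
mutate_finite_sites <- function(tree, locus_length, ts_fraction = 0.5,
                                mu = 3.18e-9, seed = 1L) {
  if (ts_fraction < 0 || ts_fraction > 1)
    stop("`ts_fraction` must be in [0, 1]", call. = FALSE)
  if (locus_length < 1) stop("`locus_length` must be >= 1", call. = FALSE)
  n <- length(tree$tip.label)
  parent <- phylo_to_parent(tree)
  # node times from branch lengths (leaves at 0 for ultrametric trees)
  nn <- length(parent)
  depth <- numeric(nn)
  root <- which(parent == -1L)
  ord <- order(vapply(seq_len(nn), function(v) node_depth_edges(parent, v),
                      numeric(1)))
  for (v in ord) if (parent[v] >= 0)
    depth[v] <- depth[parent[v] + 1L] +
      tree$edge.length[which(tree$edge[, 2] == v)]
  tmax <- max(depth)
  time <- tmax - depth
  res <- cpp_mutate_hky(parent, time, n, locus_length, mu, ts_fraction,
                        as.double(seed))
  bases <- c("A", "C", "G", "T")
  haps <- matrix(bases[res$alleles[seq_len(n), , drop = FALSE] + 1L],
                 nrow = n)
  rownames(haps) <- tree$tip.label
  out <- new_haplotype_block("locus_1", locus_length, res$positions, haps,
                             "acgt", ancestral = bases[res$ancestral + 1L])
  attr(out, "n_mutations") <- res$n_mutations
  attr(out, "n_transitions") <- res$n_transitions
  out
}

node_depth_edges <- function(parent, v) {
  d <- 0
  while (parent[v] >= 0) { v <- parent[v] + 1L; d <- d + 1 }
  d
}

#' Simulate a set of independent gene trees
#'
#' @inheritParams simulate_locus
#' @param n_loci Number of independent loci.
#' @param outgroup If `TRUE`, the model is extended with an outgroup
#'   population (Ne 1e4, 10 My divergence) before simulating.
#' @return A `multiPhylo` list of rooted trees with branch lengths in
#'   generations; per-locus seeds derive from `seed` by a counter scheme so
#'   locus i does not depend on `n_loci`.
#' @export
simulate_tree_set <- function(model, n_loci, seed, samples = NULL,
                              outgroup = FALSE) {
  if (n_loci < 1) stop("`n_loci` must be >= 1", call. = FALSE)
  if (outgroup && is.null(attr(model, "outgroup")))
    model <- attach_outgroup(model)
  es <- compile_model(model, samples)
  labs <- leaf_labels(es$pop_names, es$samples)
  gl <- cpp_sim_genealogies(es, as.integer(n_loci), as.double(seed))
  trees <- lapply(gl, function(g)
    genealogy_to_phylo(g$parent, g$time, g$n_leaves, labs))
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate a set of genealogies in raw (parent-array) form
#'
#' Same draw as [simulate_tree_set()] but without the `phylo` conversion;
#' the result feeds [topology_weight_table()] directly, which is much
#' faster for large simulated tree sets.
#'
#' @inheritParams simulate_tree_set
#' @return A `genealogy_set`: list of genealogies (`parent`, `time`,
#'   `leaf_pop`), plus `pop_names` and `samples`.
#' @export
sim_genealogy_set <- function(model, n_loci, seed, samples = NULL,
                              outgroup = FALSE) {
  if (outgroup && is.null(attr(model, "outgroup")))
    model <- attach_outgroup(model)
  es <- compile_model(model, samples)
  gl <- cpp_sim_genealogies(es, as.integer(n_loci), as.double(seed))
  structure(list(genealogies = gl, pop_names = es$pop_names,
                 samples = es$samples),
            class = "genealogy_set")
}

#' @export
print.genealogy_set <- function(x, ...) {
  cat("<genealogy_set> ", length(x$genealogies), " genealogies, ",
      sum(x$samples), " haploid samples\n", sep = "")
  invisible(x)
}

#' Write a tree set as one-tree-per-line Newick
#' @param trees A `multiPhylo`.
#' @param path Output file.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Write a haplotype block as FASTA or TSV
#'
#' Finite-sites blocks write one FASTA record per haplotype over the
#' polymorphic sites; 0/1 infinite-sites blocks write a plain TSV
#' (position column plus one 0/1 column per haplotype).
#'
#' @param block A `haplotype_block`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_block_fasta <- function(block, path) {
  if (block$alleles != "acgt")
    stop("FASTA output is for finite-sites (A/C/G/T) blocks; use ",
         "write_block_tsv() for 0/1 blocks", call. = FALSE)
  lines <- character(0)
  for (r in seq_len(nrow(block$haplotypes)))
    lines <- c(lines, paste0(">", rownames(block$haplotypes)[r]),
               paste(block$haplotypes[r, ], collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_block_fasta
#' @export
write_block_tsv <- function(block, path) {
  m <- t(block$haplotypes)
  df <- data.frame(position = block$positions, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-locus genealogy summaries
#'
#' Simulates loci and returns TMRCA, total branch length (generations) and a
#' Poisson mutation count per locus, without materialising trees.
#'
#' @inheritParams simulate_tree_set
#' @param locus_length Locus length in bp (scales the mutation count).
#' @return A tibble with columns `tmrca`, `total_length`, `n_mut`.
#' @export
simulate_locus_stats <- function(model, n_loci, locus_length, seed,
                                 samples = NULL) {
  es <- compile_model(model, samples)
  m <- cpp_sim_stats(es, as.integer(n_loci), locus_length,
                     es$mutation_rate, as.double(seed))
  tibble::as_tibble(m)
}
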