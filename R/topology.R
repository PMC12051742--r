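# Block gene trees, Twisst-style topology weighting, ternary binning and
# observed-vs-simulated comparison.

# All rooted binary topologies over taxon indices 0..n-1, as canonical
# strings: children of every internal node ordered by smallest contained
# taxon.  Matches the canonical labels emitted by the C++ classifier.
enumerate_topologies <- function(n_taxa) {
  canon <- function(set) {
    if (length(set) == 1) return(as.character(set))
    out <- character()
    rest <- set[-1]
    # first element always goes left: each unordered split once
    for (msk in 0:(2^length(rest) - 1)) {
      left <- c(set[1], rest[bitwAnd(msk, 2^(seq_along(rest) - 1)) > 0])
      right <- setdiff(set, left)
      if (length(right) == 0) next
      for (l in canon(left)) for (r in canon(right)) {
        a <- l; b <- r
        if (min(as_set(b)) < min(as_set(a))) { tmp <- a; a <- b; b <- tmp }
        out <- c(out, paste0("(", a, ",", b, ")"))
      }
    }
    unique(out)
  }
  canon(seq_len(n_taxa) - 1L)
}

as_set <- function(label) as.integer(regmatches(label,
                                                gregexpr("[0-9]+",
                                                         label))[[1]])

pretty_topology <- function(label, taxa) {
  for (i in rev(seq_along(taxa)))
    label <- gsub(paste0("\\b", i - 1L, "\\b"), taxa[i], label)
  label
}

#' Partition sorted SNPs into fixed-size blocks
#'
#' Consecutive, non-overlapping blocks of `block_size` SNPs per contig;
#' the trailing block of a contig may be shorter and is flagged.
#'
#' @param sites Tibble with columns `contig`, `pos`, sorted by contig then
#'   position (an error otherwise).
#' @param block_size SNPs per block (default 50).
#' @return Tibble: `block`, `contig`, `start`, `end`, `first`, `last`
#'   (site row indices), `n_snps`, `complete`.
#' @export
partition_blocks <- function(sites, block_size = 50) {
  if (nrow(sites) == 0)
    return(tibble::tibble(block = integer(), contig = character(),
                          start = integer(), end = integer(),
                          first = integer(), last = integer(),
                          n_snps = integer(), complete = logical()))
  ord <- order(match(sites$contig, unique(sites$contig)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("`sites` must be sorted by contig and position", call. = FALSE)
  out <- list()
  bid <- 0L
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    nb <- ceiling(length(idx) / block_size)
    for (b in seq_len(nb)) {
      ii <- idx[((b - 1) * block_size + 1):min(b * block_size,
                                               length(idx))]
      bid <- bid + 1L
      out[[bid]] <- tibble::tibble(
        block = bid, contig = ctg,
        start = sites$pos[ii[1]], end = sites$pos[ii[length(ii)]],
        first = ii[1], last = ii[length(ii)],
        n_snps = length(ii), complete = length(ii) == block_size)
    }
  }
  dplyr::bind_rows(out)
}

haplotype_names <- function(samples) {
  as.vector(rbind(paste0(samples, "_a"), paste0(samples, "_b")))
}

#' Neighbour-joining tree of one SNP block
#'
#' Builds pairwise model-corrected distances over the phased haplotypes
#' plus the haploid outgroup sequence, runs neighbour joining, roots on the
#' outgroup and clamps negative branch lengths to zero.  The distance model
#' degrades along a defined cascade (TN93 -> K80 -> JC69 -> raw) whenever a
#' model yields non-finite distances on the short alignment; the model
#' actually used is recorded in attribute `dist_model`.
#'
#' @param geno A `pop_genotypes` with `outgroup` alleles.
#' @param first,last Site-index range of the block (e.g. from
#'   [partition_blocks()]).
#' @param outgroup_label Tip label for the outgroup sequence.
#' @return A rooted `phylo`; identical sequences collapse to zero-length
#'   branches (a fully star-like block yields a star tree).
#' @export
build_block_tree <- function(geno, first, last, outgroup_label = "OUT") {
  idx <- first:last
  if (is.null(geno$outgroup))
    stop("`geno` carries no outgroup alleles", call. = FALSE)
  H <- geno$haplotypes[, idx, drop = FALSE]
  ref <- geno$sites$ref[idx]
  alt <- geno$sites$alt[idx]
  og <- geno$outgroup[idx]
  n <- nrow(H)
  ch <- matrix("n", n + 1, length(idx))
  for (k in seq_along(idx)) {
    col <- ifelse(is.na(H[, k]), "n",
                  ifelse(H[, k] == 0, tolower(ref[k]), tolower(alt[k])))
    ch[, k] <- c(col, ifelse(is.na(og[k]), "n",
                             ifelse(og[k] == 0, tolower(ref[k]),
                                    tolower(alt[k]))))
  }
  rownames(ch) <- c(haplotype_names(geno$samples), outgroup_label)
  if (nrow(ch) < 4)
    stop("at least 4 haplotypes including the outgroup are required",
         call. = FALSE)
  dna <- ape::as.DNAbin(ch)
  d <- NULL
  used <- NA_character_
  for (model in c("TN93", "K80", "JC69", "raw")) {
    dd <- suppressWarnings(ape::dist.dna(dna, model = model,
                                         pairwise.deletion = TRUE))
    if (all(is.finite(dd))) { d <- dd; used <- model; break }
  }
  if (is.null(d)) { d <- ape::dist.dna(dna, "raw", pairwise.deletion = TRUE)
                    d[!is.finite(d)] <- 0; used <- "raw" }
  if (all(d == 0)) {
    tr <- ape::stree(nrow(ch), type = "star", tip.label = rownames(ch))
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else {
    tr <- ape::nj(d)
    tr$edge.length[tr$edge.length < 0] <- 0
    tr <- ape::root(tr, outgroup = outgroup_label, resolve.root = TRUE)
  }
  attr(tr, "dist_model") <- used
  tr
}

#' Build NJ gene trees for all SNP blocks of a dataset
#'
#' @param geno A `pop_genotypes` with outgroup alleles.
#' @param block_size SNPs per block (default 50).
#' @return A list with `blocks` (tibble from [partition_blocks()]) and
#'   `trees` (a `multiPhylo`).
#' @export
block_trees <- function(geno, block_size = 50) {
  blocks <- partition_blocks(geno$sites, block_size)
  trees <- lapply(seq_len(nrow(blocks)), function(b)
    build_block_tree(geno, blocks$first[b], blocks$last[b]))
  class(trees) <- "multiPhylo"
  list(blocks = blocks, trees = trees)
}

taxon_tip_map <- function(tree, taxa) {
  tips <- tree$tip.label
  pref <- sub("_.*$", "", tips)
  lapply(setNames(taxa, taxa), function(tx) which(pref == tx) - 1L)
}

#' Topology weights of one gene tree
#'
#' Fraction of single-individual-per-taxon subtrees matching each possible
#' rooted topology (3 topologies for 3 ingroup taxa, 15 for 4).  Exact mode
#' enumerates all leaf combinations; sampled mode draws `n_iter`
#' combinations at random.  Polytomies (from zero-length branches) resolve
#' deterministically.
#'
#' @param tree A rooted `phylo` (or one rootable on `outgroup`).
#' @param taxa Character vector of taxon (population) labels; tips are
#'   assigned by their label prefix before the first underscore.
#' @param outgroup Optional outgroup tip label(s): the tree is rooted on
#'   them and they are excluded from the taxa.
#' @param mode `"auto"` (exact when the combination count fits under
#'   `cap`), `"exact"` or `"sampled"`.
#' @param n_iter Monte-Carlo iterations for sampled mode.
#' @param cap Exact-mode combination cap (default 50,000).
#' @param seed Seed for sampled mode.
#' @return Tibble: `topology` (canonical, taxon names), `weight`;
#'   attributes `mode`, `n_combinations`.
#' @export
topology_weights <- function(tree, taxa, outgroup = NULL,
                             mode = c("auto", "exact", "sampled"),
                             n_iter = 10000, cap = 50000, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.null(outgroup)) {
    og <- intersect(outgroup, tree$tip.label)
    if (length(og) > 0) {
      rooted <- tryCatch(ape::root(tree, outgroup = og,
                                   resolve.root = TRUE),
                         error = function(e) NULL)
      if (is.null(rooted))  # already rooted on the outgroup
        rooted <- ape::root(ape::unroot(tree), outgroup = og,
                            resolve.root = TRUE)
      tree <- ape::drop.tip(rooted, og)
    }
  }
  tmap <- taxon_tip_map(tree, taxa)
  sizes <- vapply(tmap, length, integer(1))
  if (any(sizes == 0))
    stop("taxa without tips: ",
         paste(taxa[sizes == 0], collapse = ", "), call. = FALSE)
  n_comb <- prod(sizes)
  if (mode == "auto") mode <- if (n_comb <= cap) "exact" else "sampled"
  parent <- phylo_to_parent(tree)
  res <- cpp_topo_weights(parent, unname(tmap), mode == "exact",
                          as.integer(n_iter), cap, as.double(seed))
  full <- enumerate_topologies(length(taxa))
  w <- setNames(rep(0, length(full)), full)
  w[res$topology] <- res$count / sum(res$count)
  out <- tibble::tibble(topology = pretty_topology(full, taxa),
                        weight = unname(w))
  attr(out, "mode") <- mode
  attr(out, "n_combinations") <- res$n_combinations
  out
}

#' Topology-weight table over a set of gene trees
#'
#' @param trees A `multiPhylo` (or list of `phylo`).
#' @param taxa Taxon labels, as in [topology_weights()].
#' @param outgroup Optional outgroup tip label(s).
#' @inheritParams topology_weights
#' @return A tibble with one row per tree (`block` id) and one weight
#'   column per topology; attribute `topologies` stores the column-label
#'   mapping.  For three taxa the columns are ordered `topo1` =
#'   (taxon1, taxon3) sisters, `topo2` = (taxon2, taxon3), `topo3` =
#'   (taxon1, taxon2), matching the conventional trio labelling.
#' @export
topology_weight_table <- function(trees, taxa, outgroup = NULL,
                                  mode = c("auto", "exact", "sampled"),
                                  n_iter = 10000, cap = 50000, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(trees, "genealogy_set")) {
    # simulated genealogies are already rooted: classify on the parent
    # arrays directly (excluding outgroup leaves from the taxa suffices)
    full <- enumerate_topologies(length(taxa))
    ti <- match(taxa, trees$pop_names)
    if (anyNA(ti)) stop("unknown taxa: ",
                        paste(taxa[is.na(ti)], collapse = ", "),
                        call. = FALSE)
    rows <- lapply(seq_along(trees$genealogies), function(i) {
      g <- trees$genealogies[[i]]
      tmap <- lapply(ti, function(t) which(g$leaf_pop == t - 1L) - 1L)
      n_comb <- prod(vapply(tmap, length, integer(1)))
      md <- if (mode == "auto") {
        if (n_comb <= cap) "exact" else "sampled"
      } else mode
      res <- cpp_topo_weights(g$parent, tmap, md == "exact",
                              as.integer(n_iter), cap,
                              as.double(seed) + i)
      w <- setNames(rep(0, length(full)), full)
      w[res$topology] <- res$count / sum(res$count)
      setNames(w, pretty_topology(full, taxa))
    })
    tab <- dplyr::bind_rows(rows)
  } else {
    rows <- lapply(seq_along(trees), function(i) {
      w <- topology_weights(trees[[i]], taxa, outgroup, mode, n_iter, cap,
                            seed = as.double(seed) + i)
      setNames(w$weight, w$topology)
    })
    tab <- dplyr::bind_rows(rows)
  }
  if (length(taxa) == 3) {
    want <- c(pretty_topology("((0,2),1)", taxa),
              pretty_topology("(0,(1,2))", taxa),
              pretty_topology("((0,1),2)", taxa))
    tab <- tab[, want]
    names(tab) <- c("topo1", "topo2", "topo3")
    attr(tab, "topologies") <- setNames(want, names(tab))
  } else {
    attr(tab, "topologies") <- setNames(names(tab), names(tab))
  }
  tab <- tibble::add_column(tab, block = seq_len(nrow(tab)), .before = 1)
  tab
}

# ---------------------------------------------------------------------------
# Ternary binning of 3-topology weights.

up_cell_index <- function(a, b, k) a * k - a * (a - 1) / 2 + b + 1

#' Bin 3-topology weights on a subdivided ternary simplex
#'
#' The simplex is subdivided into `k^2` congruent triangular cells (k = 20
#' gives 400).  Each block's weight vector is assigned to the cell
#' containing it; lattice points on cell boundaries go to the
#' lowest-index adjacent cell.
#'
#' @param weights A tibble/matrix whose first three weight columns sum to 1
#'   per row (tolerance 1e-9; a `block` column is ignored).
#' @param k Subdivision factor (default 20).
#' @return A `ternary_grid`: tibble `cell`, `a`, `b`, `orient`
#'   (up/down), `count`; attributes `k`, `total`.
#' @export
ternary_bin <- function(weights, k = 20) {
  W <- as.matrix(weights[, setdiff(colnames(weights), "block")])
  if (ncol(W) != 3)
    stop("exactly 3 topology-weight columns are required", call. = FALSE)
  if (any(abs(rowSums(W) - 1) > 1e-9))
    stop("normalisation error: weights must sum to 1 per block",
         call. = FALSE)
  cells <- ternary_cells(k)
  counts <- setNames(rep(0L, nrow(cells)), cells$cell)
  for (r in seq_len(nrow(W))) {
    a <- min(floor(k * W[r, 1]), k - 1)
    b <- min(floor(k * W[r, 2]), k - 1)
    cc <- min(floor(k * W[r, 3]), k - 1)
    s <- a + b + cc
    if (s == k - 1) {
      id <- up_cell_index(a, b, k)
    } else if (s == k - 2) {
      id <- k * (k + 1) / 2 + down_cell_index(a, b, k)
    } else {
      # lattice vertex: lowest-index adjacent up cell
      cand <- rbind(c(a - 1, b), c(a, b - 1), c(a, b))
      cand <- cand[cand[, 1] >= 0 & cand[, 2] >= 0 &
                     rowSums(cand) <= k - 1, , drop = FALSE]
      id <- min(up_cell_index(cand[, 1], cand[, 2], k))
    }
    counts[id] <- counts[id] + 1L
  }
  cells$count <- unname(counts)
  attr(cells, "k") <- k
  attr(cells, "total") <- nrow(W)
  class(cells) <- c("ternary_grid", class(cells))
  cells
}

down_cell_index <- function(a, b, k)
  a * (k - 1) - a * (a - 1) / 2 + b + 1

ternary_cells <- function(k) {
  ups <- list(); dns <- list()
  for (a in 0:(k - 1)) {
    bs <- 0:(k - 1 - a)
    ups[[a + 1]] <- tibble::tibble(a = a, b = bs, orient = "up")
    if (a <= k - 2) {
      bd <- 0:(k - 2 - a)
      dns[[a + 1]] <- tibble::tibble(a = a, b = bd, orient = "down")
    }
  }
  cells <- dplyr::bind_rows(c(ups, dns))
  cells <- tibble::add_column(cells, cell = seq_len(nrow(cells)),
                              .before = 1)
  cells
}

#' Compare observed and simulated ternary distributions
#'
#' Rescales the simulated counts to the observed total and reports the
#' per-bin difference (simulated - observed) and the summary L1 distance.
#'
#' @param observed,simulated `ternary_grid` objects with the same `k`.
#' @return Tibble `cell`, `a`, `b`, `orient`, `observed`, `simulated`
#'   (rescaled), `difference`; attribute `L1`.
#' @export
compare_ternary <- function(observed, simulated) {
  if (!identical(attr(observed, "k"), attr(simulated, "k")))
    stop("grids have different subdivision factors", call. = FALSE)
  scale <- attr(observed, "total") / max(attr(simulated, "total"), 1)
  out <- tibble::tibble(cell = observed$cell, a = observed$a,
                        b = observed$b, orient = observed$orient,
                        observed = observed$count,
                        simulated = simulated$count * scale)
  out$difference <- out$simulated - out$observed
  attr(out, "L1") <- sum(abs(out$difference))
  out
}
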