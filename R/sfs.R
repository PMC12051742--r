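# Folded joint site-frequency spectra: construction from genotypes,
# 14-bin reduction, simulation-based expectation, composite likelihood.

new_jsfs <- function(mat, pops, nA, nB, n_skipped = 0L) {
  stopifnot(nrow(mat) == nA + 1, ncol(mat) == nB + 1)
  mat[1, 1] <- 0
  mat[nA + 1, nB + 1] <- 0
  dimnames(mat) <- list(paste0("dA", 0:nA), paste0("dB", 0:nB))
  structure(list(matrix = mat, pops = pops, nA = nA, nB = nB,
                 n_sites = sum(mat), n_skipped = n_skipped),
            class = "jsfs")
}

#' @export
print.jsfs <- function(x, ...) {
  cat("<jsfs> ", x$pops[1], " (n=", x$nA, ") x ", x$pops[2], " (n=", x$nB,
      "), folded, ", format(x$n_sites, big.mark = ","),
      " polymorphic sites\n", sep = "")
  invisible(x)
}

#' @describeIn folded_jsfs Tidy a joint SFS into a tibble of cells.
#' @param x A `jsfs` object.
#' @param ... Unused.
#' @export
tidy.jsfs <- function(x, ...) {
  tibble::tibble(iA = rep(0:x$nA, times = x$nB + 1),
                 iB = rep(0:x$nB, each = x$nA + 1),
                 count = as.vector(x$matrix))
}

# Fold an unfolded count/probability matrix: cell (i, j) merges with its
# complement (nA-i, nB-j); the cell with the smaller i+j receives the mass;
# exact ties go to the smaller first index (then smaller second).
fold_matrix <- function(mat) {
  nA <- nrow(mat) - 1L
  nB <- ncol(mat) - 1L
  out <- matrix(0, nA + 1L, nB + 1L)
  for (i in 0:nA) for (j in 0:nB) {
    ci <- nA - i; cj <- nB - j
    keep <- if (i + j < ci + cj) TRUE
            else if (i + j > ci + cj) FALSE
            else if (i != ci) i < ci
            else j <= cj
    if (keep) out[i + 1, j + 1] <- mat[i + 1, j + 1] +
        (if (i != ci || j != cj) mat[ci + 1, cj + 1] else 0)
  }
  out
}

#' Folded joint site-frequency spectrum of a population pair
#'
#' Per biallelic site the alternate-allele counts `(i, j)` in the two
#' populations are folded with the complementary cell `(nA-i, nB-j)`; the
#' cell with the smaller total minor count receives the site, exact ties go
#' to the smaller first index, and the monomorphic corners are masked.
#'
#' @param geno A `pop_genotypes` object (see [read_pop_genotypes()]) or a
#'   0/1 haplotype matrix (haplotypes in rows) with a `pop` vector.
#' @param popA,popB Population labels (disjoint).
#' @param mode `"complete_case"` (drop sites with missing calls in either
#'   population) or `"projection"` (hypergeometric projection down to
#'   `project` haploid sizes).
#' @param project Integer vector `c(nA, nB)` of target haploid sizes for
#'   projection mode.
#' @param pop Population assignment per haplotype row when `geno` is a bare
#'   matrix.
#' @return A `jsfs` object: folded count matrix of shape
#'   `(nA+1) x (nB+1)` with masked corners, plus metadata.
#' @export
folded_jsfs <- function(geno, popA, popB, mode = c("complete_case",
                                                   "projection"),
                        project = NULL, pop = NULL) {
  mode <- match.arg(mode)
  if (inherits(geno, "pop_genotypes")) {
    pop <- geno$pop
    H <- geno$haplotypes
  } else {
    H <- geno
    if (is.null(pop)) stop("`pop` required for a bare matrix", call. = FALSE)
  }
  if (identical(popA, popB)) stop("populations must be disjoint",
                                  call. = FALSE)
  ra <- which(pop == popA)
  rb <- which(pop == popB)
  if (length(ra) == 0 || length(rb) == 0)
    stop("empty population: ", if (length(ra) == 0) popA else popB,
         call. = FALSE)
  HA <- H[ra, , drop = FALSE]
  HB <- H[rb, , drop = FALSE]
  okA <- colSums(is.na(HA)) == 0
  okB <- colSums(is.na(HB)) == 0
  if (mode == "complete_case") {
    use <- okA & okB
    iA <- colSums(HA[, use, drop = FALSE])
    iB <- colSums(HB[, use, drop = FALSE])
    nA <- length(ra); nB <- length(rb)
    un <- matrix(0, nA + 1, nB + 1)
    for (k in seq_along(iA)) un[iA[k] + 1, iB[k] + 1] <-
        un[iA[k] + 1, iB[k] + 1] + 1
    out <- new_jsfs(fold_matrix(un), c(popA, popB), nA, nB,
                    n_skipped = sum(!(okA & okB)))
  } else {
    if (is.null(project) || length(project) != 2)
      stop("`project` must be c(nA, nB)", call. = FALSE)
    nA <- project[1]; nB <- project[2]
    un <- matrix(0, nA + 1, nB + 1)
    skipped <- 0L
    cA <- colSums(HA, na.rm = TRUE); mA <- colSums(!is.na(HA))
    cB <- colSums(HB, na.rm = TRUE); mB <- colSums(!is.na(HB))
    for (k in seq_along(cA)) {
      if (mA[k] < nA || mB[k] < nB) { skipped <- skipped + 1L; next }
      pa <- stats::dhyper(0:nA, cA[k], mA[k] - cA[k], nA)
      pb <- stats::dhyper(0:nB, cB[k], mB[k] - cB[k], nB)
      un <- un + outer(pa, pb)
    }
    out <- new_jsfs(fold_matrix(un), c(popA, popB), nA, nB,
                    n_skipped = skipped)
  }
  out
}

#' Reduce a joint SFS to the 14 coarse polymorphism bins
#'
#' Each axis is categorised as absent (0), singleton, interior (2..n-1) or
#' fixed (n); the 4 x 4 grid minus the two fully-monomorphic corners gives
#' 14 named bins whose counts sum to the SFS total.
#'
#' @param jsfs A `jsfs` object with at least 2 haploids per population.
#' @return A tibble with columns `bin_A`, `bin_B`, `count` (14 rows) and
#'   attribute `provenance`.
#' @export
bin_jsfs_14 <- function(jsfs) {
  if (jsfs$nA < 2 || jsfs$nB < 2)
    stop("binning requires at least 2 haploids per population",
         call. = FALSE)
  cat_of <- function(i, n)
    dplyr::case_when(i == 0 ~ "0", i == 1 ~ "singleton",
                     i == n ~ "fixed", TRUE ~ "interior")
  cells <- tidy.jsfs(jsfs)
  cells$bin_A <- cat_of(cells$iA, jsfs$nA)
  cells$bin_B <- cat_of(cells$iB, jsfs$nB)
  lv <- c("0", "singleton", "interior", "fixed")
  grid <- tidyr::expand_grid(bin_A = lv, bin_B = lv)
  grid <- grid[!(grid$bin_A == "0" & grid$bin_B == "0") &
               !(grid$bin_A == "fixed" & grid$bin_B == "fixed"), ]
  agg <- dplyr::summarise(dplyr::group_by(cells, .data$bin_A, .data$bin_B),
                          count = sum(.data$count), .groups = "drop")
  out <- dplyr::left_join(grid, agg, by = c("bin_A", "bin_B"))
  out$count[is.na(out$count)] <- 0
  # masked corner cells carry no mass, so dropping the two corner bins
  # conserves the total exactly
  attr(out, "provenance") <- paste(jsfs$pops, collapse = "-")
  out
}

#' Simulation-based expected folded joint SFS
#'
#' Monte-Carlo estimate of the per-polymorphic-site probability of each
#' folded cell, from expected branch lengths (or Poisson mutation counts)
#' over independent simulated loci.
#'
#' @param model A `demographic_model`.
#' @param pair Character vector of two population names.
#' @param n_sim_loci Number of simulated loci.
#' @param locus_length Locus length in bp.
#' @param seed Integer seed.
#' @param poisson If `TRUE`, sample Poisson mutation counts instead of
#'   accumulating expected branch lengths (noisier; used for observed-like
#'   data).
#' @param p_floor Zero-probability floor applied before use in a log
#'   likelihood (renormalised).
#' @return A probability matrix (folded, corners masked) whose unmasked
#'   cells sum to 1, of class `jsfs_expected`.
#' @export
expected_jsfs <- function(model, pair, n_sim_loci, locus_length = 2000,
                          seed = 1L, poisson = FALSE, p_floor = 1e-8) {
  if (n_sim_loci < 1) stop("`n_sim_loci` must be >= 1", call. = FALSE)
  res <- expected_jsfs_set(model, list(pair), n_sim_loci, locus_length,
                           seed, poisson, p_floor)
  res[[1]]
}

# Expectations for several pairs from one simulation pass.
expected_jsfs_set <- function(model, pairs, n_sim_loci, locus_length = 2000,
                              seed = 1L, poisson = FALSE, p_floor = 1e-8) {
  es <- compile_model(model)
  pn <- es$pop_names
  pidx <- vapply(pairs, function(pr) {
    i <- match(pr, pn)
    if (anyNA(i)) stop("unknown population in pair: ",
                       paste(pr, collapse = ","), call. = FALSE)
    i - 1L
  }, integer(2))
  mats <- cpp_sim_jsfs(es, as.integer(n_sim_loci), locus_length,
                       es$mutation_rate, t(pidx), as.double(seed), poisson)
  out <- lapply(seq_along(pairs), function(k) {
    f <- fold_matrix(mats[[k]])
    nA <- nrow(f) - 1L; nB <- ncol(f) - 1L
    f[1, 1] <- 0
    f[nA + 1, nB + 1] <- 0
    tot <- sum(f)
    p <- if (tot > 0) f / tot else f
    if (p_floor > 0) {
      mask <- matrix(TRUE, nA + 1, nB + 1)
      mask[1, 1] <- FALSE
      # only cells reachable after folding can carry probability
      reach <- fold_matrix(matrix(1, nA + 1, nB + 1)) > 0
      mask <- mask & reach
      p[mask & p < p_floor] <- p_floor
      p[!mask] <- 0
      p <- p / sum(p)
    }
    structure(p, class = "jsfs_expected", pops = pairs[[k]])
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "-")
  out
}

#' Multinomial composite log-likelihood of an observed SFS
#'
#' Treats sites as independent: `sum(O_c * log10(p_c))` over cells.
#'
#' @param obs A `jsfs`, a numeric matrix of counts, or a binned-SFS tibble
#'   with a `count` column.
#' @param expected Matching probabilities (matrix or vector).
#' @return The log10 composite likelihood (a scalar).
#' @export
composite_loglik <- function(obs, expected) {
  o <- if (inherits(obs, "jsfs")) obs$matrix
       else if (is.data.frame(obs)) obs$count
       else obs
  p <- if (is.data.frame(expected)) expected$count else unclass(expected)
  if (length(o) != length(p))
    stop("observed and expected shapes differ", call. = FALSE)
  use <- o > 0
  if (any(p[use] <= 0))
    stop("expected probability is zero where observations exist; ",
         "apply a probability floor", call. = FALSE)
  sum(o[use] * log10(p[use]))
}

#' Akaike information criterion from a log10 composite likelihood
#'
#' `AIC = 2k - 2 ln(10) log10(L)`, i.e. the natural-log likelihood
#' expressed through the reported log10 value.
#'
#' @param log10_L Composite log-likelihood in log10 units.
#' @param k Number of free parameters (>= 0).
#' @return The AIC value.
#' @examples
#' aic(-10, 2)  # 4 + 2*ln(10)*10
#' @export
aic <- function(log10_L, k) {
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  2 * k - 2 * log(10) * log10_L
}

#' Neutral genome length scaling
#'
#' Scales the genome length to the unlinked putatively-neutral fraction:
#' `n_snps_used / n_total_neutral_snps * (n_total_neutral_snps +
#' n_neutral_invariant)`, rounded to the nearest bp.
#'
#' @param n_snps_used Number of SNPs entering the analysis.
#' @param n_total_neutral_snps Total neutral SNPs.
#' @param n_neutral_invariant Total neutral invariant sites.
#' @return Scaled length in bp (integer-valued numeric).
#' @export
neutral_genome_scaling <- function(n_snps_used, n_total_neutral_snps,
                                   n_neutral_invariant) {
  if (n_snps_used <= 0 || n_total_neutral_snps <= 0 ||
      n_neutral_invariant <= 0)
    stop("all counts must be > 0", call. = FALSE)
  if (n_snps_used > n_total_neutral_snps)
    stop("`n_snps_used` cannot exceed `n_total_neutral_snps`",
         call. = FALSE)
  round(n_snps_used / n_total_neutral_snps *
          (n_total_neutral_snps + n_neutral_invariant))
}

#' Number of bootstrap loci covering the scaled neutral genome
#'
#' @param n_neutral_snps Total neutral SNPs.
#' @param n_neutral_invariant Total neutral invariant sites.
#' @param locus_length Bootstrap locus length in bp (default 1000).
#' @return `ceiling((n_neutral_snps + n_neutral_invariant) / locus_length)`.
#' @export
bootstrap_locus_count <- function(n_neutral_snps, n_neutral_invariant,
                                  locus_length = 1000) {
  ceiling((n_neutral_snps + n_neutral_invariant) / locus_length)
}

# ---------------------------------------------------------------------------
# fastsimcoal-style .obs dialect and a self-describing TSV.

#' Write / read a folded joint SFS in a fastsimcoal-style .obs dialect
#'
#' Line 1: `1 observations`; line 2: the haploid sample sizes; then the
#' `(nA+1) x (nB+1)` matrix, rows = popA counts.
#'
#' @param jsfs A `jsfs` object.
#' @param path File path.
#' @return `read_jsfs_obs` returns a `jsfs`; the writer returns the path
#'   invisibly.
#' @export
write_jsfs_obs <- function(jsfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("1 observations", con)
  writeLines(paste(jsfs$nA, jsfs$nB, paste(jsfs$pops, collapse = " ")), con)
  utils::write.table(jsfs$matrix, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn write_jsfs_obs Self-describing TSV (one row per folded
#'   cell: `pop_a`, `pop_b`, `n_a`, `n_b`, `iA`, `iB`, `count`).
#' @export
write_jsfs_tsv <- function(jsfs, path) {
  df <- tidy.jsfs(jsfs)
  df <- data.frame(pop_a = jsfs$pops[1], pop_b = jsfs$pops[2],
                   n_a = jsfs$nA, n_b = jsfs$nB, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn write_jsfs_obs Read the self-describing TSV back.
#' @export
read_jsfs_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  nA <- df$n_a[1]; nB <- df$n_b[1]
  mat <- matrix(0, nA + 1, nB + 1)
  mat[cbind(df$iA + 1, df$iB + 1)] <- df$count
  new_jsfs(mat, c(df$pop_a[1], df$pop_b[1]), nA, nB)
}

#' @rdname write_jsfs_obs
#' @export
read_jsfs_obs <- function(path) {
  lines <- readLines(path)
  if (!grepl("observations", lines[1]))
    stop("not a .obs file: missing observations header", call. = FALSE)
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  nA <- as.integer(hdr[1]); nB <- as.integer(hdr[2])
  pops <- if (length(hdr) >= 4) hdr[3:4] else c("popA", "popB")
  mat <- as.matrix(utils::read.table(text = lines[3:(3 + nA)], sep = "\t"))
  dimnames(mat) <- NULL
  new_jsfs(mat, pops, nA, nB)
}
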