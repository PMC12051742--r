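# Windowed diversity/divergence statistics, introgression statistics,
# four-gamete recombination fraction, HWE filtering, Tajima's D.

pop_allele_counts <- function(H, pop, pops) {
  lapply(setNames(pops, pops), function(p) {
    sub <- H[pop == p, , drop = FALSE]
    list(c = colSums(sub, na.rm = TRUE), n = colSums(!is.na(sub)))
  })
}

#' Windowed diversity and divergence statistics
#'
#' Computes nucleotide diversity (pi, mean pairwise differences per
#' accessible site), absolute divergence d_XY, Hudson's F_ST (ratio of
#' sums per window) and net divergence d_a = d_XY - (pi_x + pi_y)/2 in
#' fixed-width windows along each contig.  Monomorphic-but-accessible
#' sites enter through the accessible-site denominators.
#'
#' @param geno A `pop_genotypes` object.
#' @param window_size Window width in bp (default 50,000).
#' @param mask Optional accessibility mask: tibble `contig`, `start`,
#'   `end` (1-based inclusive).  Default: every site of every declared
#'   contig is accessible.
#' @param pops Populations to include (default: all).
#' @return A tibble in long form: `contig`, `start`, `end`,
#'   `n_accessible`, `n_variant`, `stat` (pi/dxy/fst/da), `pop_a`,
#'   `pop_b` (NA for within-population stats), `value`.  Windows with no
#'   accessible sites carry `NA` values.
#' @export
window_stats <- function(geno, window_size = 50000, mask = NULL,
                         pops = NULL) {
  if (is.null(pops)) pops <- unique(geno$pop)
  H <- geno$haplotypes
  sites <- geno$sites
  ac <- pop_allele_counts(H, geno$pop, pops)
  win_start <- ((sites$pos - 1) %/% window_size) * window_size + 1
  key <- paste(sites$contig, win_start)

  # accessible length per window
  wins <- window_frame(geno$contigs, window_size, mask)
  wkey <- paste(wins$contig, wins$start)

  per_site <- list()
  for (p in pops) {
    cc <- ac[[p]]$c; nn <- ac[[p]]$n
    pi_s <- ifelse(nn >= 2, 2 * cc * (nn - cc) / (nn * pmax(nn - 1, 1)), NA)
    per_site[[paste0("pi|", p)]] <- pi_s
  }
  pair_idx <- if (length(pops) >= 2) utils::combn(pops, 2)
              else matrix(character(), 2, 0)
  for (k in seq_len(ncol(pair_idx))) {
    a <- pair_idx[1, k]; b <- pair_idx[2, k]
    ca <- ac[[a]]$c; na <- ac[[a]]$n
    cb <- ac[[b]]$c; nb <- ac[[b]]$n
    ok <- na >= 2 & nb >= 2
    pa <- ca / na; pb <- cb / nb
    dxy <- (ca * (nb - cb) + cb * (na - ca)) / (na * nb)
    fst_num <- (pa - pb)^2 - pa * (1 - pa) / pmax(na - 1, 1) -
      pb * (1 - pb) / pmax(nb - 1, 1)
    fst_den <- pa * (1 - pb) + pb * (1 - pa)
    dxy[!ok] <- NA; fst_num[!ok] <- NA; fst_den[!ok] <- NA
    per_site[[paste0("dxy|", a, "|", b)]] <- dxy
    per_site[[paste0("fstnum|", a, "|", b)]] <- fst_num
    per_site[[paste0("fstden|", a, "|", b)]] <- fst_den
  }
  sums <- lapply(per_site, function(v)
    tapply(v, key, sum, na.rm = TRUE))
  n_var <- tapply(rep(1, nrow(sites)), key, sum)

  out <- list()
  for (w in seq_len(nrow(wins))) {
    kk <- wkey[w]
    acc <- wins$n_accessible[w]
    nv <- if (kk %in% names(n_var)) unname(n_var[[kk]]) else 0
    gv <- function(nm) {
      if (acc == 0) return(NA_real_)
      s <- sums[[nm]]
      if (kk %in% names(s)) unname(s[[kk]]) else 0
    }
    rows <- list()
    pis <- setNames(vapply(pops, function(p) {
      v <- gv(paste0("pi|", p))
      if (is.na(v)) NA_real_ else v / acc
    }, numeric(1)), pops)
    for (p in pops)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stat = "pi", pop_a = p, pop_b = NA_character_, value = pis[[p]])
    for (k in seq_len(ncol(pair_idx))) {
      a <- pair_idx[1, k]; b <- pair_idx[2, k]
      dxy <- gv(paste0("dxy|", a, "|", b))
      dxy <- if (is.na(dxy)) NA_real_ else dxy / acc
      fn <- gv(paste0("fstnum|", a, "|", b))
      fd <- gv(paste0("fstden|", a, "|", b))
      fst <- if (is.na(fn) || is.na(fd) || fd == 0) NA_real_ else fn / fd
      da <- dxy - (pis[[a]] + pis[[b]]) / 2
      rows[[length(rows) + 1]] <- tibble::tibble(
        stat = c("dxy", "fst", "da"), pop_a = a, pop_b = b,
        value = c(dxy, fst, da))
    }
    out[[w]] <- dplyr::bind_rows(rows)
    out[[w]]$contig <- wins$contig[w]
    out[[w]]$start <- wins$start[w]
    out[[w]]$end <- wins$end[w]
    out[[w]]$n_accessible <- acc
    out[[w]]$n_variant <- nv
  }
  res <- dplyr::bind_rows(out)
  dplyr::select(res, "contig", "start", "end", "n_accessible",
                "n_variant", "stat", "pop_a", "pop_b", "value")
}

window_frame <- function(contigs, window_size, mask = NULL) {
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    len <- contigs$length[i]
    starts <- seq(1, len, by = window_size)
    ends <- pmin(starts + window_size - 1, len)
    acc <- ends - starts + 1
    if (!is.null(mask)) {
      msk <- mask[mask$contig == contigs$contig[i], , drop = FALSE]
      acc <- vapply(seq_along(starts), function(w) {
        if (nrow(msk) == 0) return(0)
        ov <- pmin(msk$end, ends[w]) - pmax(msk$start, starts[w]) + 1
        sum(pmax(ov, 0))
      }, numeric(1))
    }
    rows[[i]] <- tibble::tibble(contig = contigs$contig[i],
                                start = starts, end = ends,
                                n_accessible = acc)
  }
  dplyr::bind_rows(rows)
}

#' Net divergence
#'
#' `d_a = d_XY - (pi_x + pi_y) / 2`; may be negative (reported as-is).
#'
#' @param d_xy Absolute divergence.
#' @param pi_x,pi_y Within-population diversities.
#' @return The net divergence.
#' @export
net_divergence <- function(d_xy, pi_x, pi_y) d_xy - (pi_x + pi_y) / 2

#' Convert net divergence to years
#'
#' Assumes all net divergence accumulated after the split:
#' `T = d_a / (2 mu) * generation_time`.
#'
#' @param d_a Net divergence per site (> 0; otherwise `NA` is returned).
#' @param config A [global_config()].
#' @return Divergence time in years.
#' @export
da_to_years <- function(d_a, config = global_config()) {
  ifelse(d_a > 0,
         d_a / (2 * config$mutation_rate) * config$generation_time,
         NA_real_)
}

#' Polarised derived-allele frequencies
#'
#' Uses the haploid outgroup allele to orient each site: the derived allele
#' is the one the outgroup does not carry.  Sites without an outgroup call
#' are dropped.
#'
#' @param geno A `pop_genotypes` with an `outgroup` component.
#' @param pops Populations to tabulate.
#' @return Tibble: `contig`, `pos` plus one frequency column per
#'   population (NaN where a population has no calls).
#' @export
derived_freqs <- function(geno, pops = NULL) {
  if (is.null(geno$outgroup))
    stop("`geno` carries no outgroup alleles", call. = FALSE)
  if (is.null(pops)) pops <- unique(geno$pop)
  keep <- !is.na(geno$outgroup)
  og <- geno$outgroup[keep]
  out <- geno$sites[keep, c("contig", "pos")]
  for (p in pops) {
    sub <- geno$haplotypes[geno$pop == p, keep, drop = FALSE]
    f_alt <- colSums(sub, na.rm = TRUE) / colSums(!is.na(sub))
    out[[p]] <- ifelse(og == 1, 1 - f_alt, f_alt)
  }
  out
}

#' Patterson's D (ABBA-BABA)
#'
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` with
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)` per site,
#' and a delete-one block-jackknife standard error.
#'
#' @param p1,p2,p3,pO Per-site derived-allele frequencies for the
#'   populations of the arrangement `(((P1, P2), P3), O)`.
#' @param block Optional per-site block id for the jackknife (e.g. 5-Mb
#'   blocks); fewer than 2 blocks, or absent, yields `NA` SE.
#' @return A one-row tibble: `D`, `se`, `z`, `n_sites`, `n_blocks`,
#'   `abba`, `baba`.  `D` is `NA` (flagged) when the denominator is zero.
#' @export
patterson_d <- function(p1, p2, p3, pO, block = NULL) {
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  ok <- !is.na(abba) & !is.na(baba)
  abba <- abba[ok]; baba <- baba[ok]
  den <- sum(abba + baba)
  D <- if (den == 0) NA_real_ else sum(abba - baba) / den
  se <- NA_real_
  nb <- 0L
  if (!is.null(block) && !is.na(D)) {
    block <- block[ok]
    ub <- unique(block)
    nb <- length(ub)
    if (nb >= 2) {
      loo <- vapply(ub, function(b) {
        keep <- block != b
        d <- sum(abba[keep] + baba[keep])
        if (d == 0) return(NA_real_)
        sum(abba[keep] - baba[keep]) / d
      }, numeric(1))
      loo <- loo[!is.na(loo)]
      se <- sqrt((length(loo) - 1) / length(loo) *
                   sum((loo - mean(loo))^2))
    }
  }
  tibble::tibble(D = D, se = se, z = D / se, n_sites = length(abba),
                 n_blocks = nb, abba = sum(abba), baba = sum(baba))
}

#' f4 statistic and f4-ratio
#'
#' `f4(A, B; C, D) = mean((pA - pB) * (pC - pD))` over sites; the f4-ratio
#' `alpha = f4(A, O; X, C) / f4(A, O; B, C)` estimates the ancestry
#' proportion of the admixed population X deriving from the B side, where
#' A is the unadmixed relative of the donor B's sister lineage and C the
#' unadmixed relative on X's original side.
#'
#' @param pA,pO,pX,pB,pC Per-site derived-allele frequencies.
#' @param block Optional per-site block id for a jackknife SE.
#' @return One-row tibble: `alpha`, `se`, `f4_num`, `f4_den`, `unstable`
#'   (TRUE when the denominator is within 2 jackknife SEs of zero).
#' @export
f4_ratio <- function(pA, pO, pX, pB, pC, block = NULL) {
  num_s <- (pA - pO) * (pX - pC)
  den_s <- (pA - pO) * (pB - pC)
  ok <- !is.na(num_s) & !is.na(den_s)
  num_s <- num_s[ok]; den_s <- den_s[ok]
  num <- sum(num_s); den <- sum(den_s)
  alpha <- if (abs(den) < .Machine$double.eps) NA_real_ else num / den
  se <- NA_real_
  den_se <- NA_real_
  if (!is.null(block)) {
    block <- block[ok]
    ub <- unique(block)
    if (length(ub) >= 2) {
      loo <- vapply(ub, function(b) {
        keep <- block != b
        sum(num_s[keep]) / sum(den_s[keep])
      }, numeric(1))
      loo <- loo[is.finite(loo)]
      if (length(loo) >= 2)
        se <- sqrt((length(loo) - 1) / length(loo) *
                     sum((loo - mean(loo))^2))
      lood <- vapply(ub, function(b) sum(den_s[block != b]), numeric(1))
      den_se <- sqrt((length(ub) - 1) / length(ub) *
                       sum((lood - mean(lood))^2))
    }
  }
  tibble::tibble(alpha = alpha, se = se, f4_num = num, f4_den = den,
                 unstable = !is.na(den_se) & abs(den) < 2 * den_se)
}

#' Windowed f_dM introgression statistic
#'
#' Malinsky's symmetric modification of Martin's f_d, computed in
#' non-overlapping windows of `window_snps` polarisable SNPs for the
#' arrangement `(((P1, P2), P3), O)`.  Positive values indicate excess
#' allele sharing between P2 and P3, negative between P1 and P3.  The
#' dynamic donor is whichever of the compared populations has the higher
#' derived frequency at each site.
#'
#' @param geno A `pop_genotypes` with outgroup alleles.
#' @param p1,p2,p3 Population labels for the trio.
#' @param window_snps SNPs per window (default 50).
#' @return Tibble: `contig`, `start`, `end`, `n_snps`, `fdm` (NA where the
#'   window denominator is undefined).
#' @export
fdm_windows <- function(geno, p1, p2, p3, window_snps = 50) {
  fr <- derived_freqs(geno, c(p1, p2, p3))
  q1 <- fr[[p1]]; q2 <- fr[[p2]]; q3 <- fr[[p3]]
  ok <- !is.na(q1) & !is.na(q2) & !is.na(q3)
  fr <- fr[ok, ]; q1 <- q1[ok]; q2 <- q2[ok]; q3 <- q3[ok]
  S <- function(a, b, c) (1 - a) * b * c - a * (1 - b) * c
  num <- S(q1, q2, q3)
  den <- numeric(length(num))
  hi23 <- pmax(q2, q3)
  hi13 <- pmax(q1, q3)
  up <- q2 >= q1
  den[up] <- S(q1[up], hi23[up], hi23[up])
  den[!up] <- -S(hi13[!up], q2[!up], hi13[!up])
  out <- list()
  for (ctg in unique(fr$contig)) {
    idx <- which(fr$contig == ctg)
    nw <- ceiling(length(idx) / window_snps)
    for (w in seq_len(nw)) {
      ii <- idx[((w - 1) * window_snps + 1):min(w * window_snps,
                                                length(idx))]
      dsum <- sum(den[ii])
      out[[length(out) + 1]] <- tibble::tibble(
        contig = ctg, start = min(fr$pos[ii]), end = max(fr$pos[ii]),
        n_snps = length(ii),
        fdm = if (dsum == 0) NA_real_ else sum(num[ii]) / dsum)
    }
  }
  dplyr::bind_rows(out)
}

#' Correlation of per-contig introgression with contig length
#'
#' Pearson correlation (two-sided) of chromosome-mean f_dM against
#' chromosome length, the paper-style recombination-proxy test.
#'
#' @param fdm Tibble with columns `contig` and `fdm` (e.g. from
#'   [fdm_windows()]), or per-contig means.
#' @param contig_lengths Tibble `contig`, `length`.
#' @return One-row tibble: `r`, `p`, `n_contigs` (`NA` + flag when fewer
#'   than 3 contigs or a constant vector).
#' @export
length_vs_introgression <- function(fdm, contig_lengths) {
  m <- dplyr::summarise(dplyr::group_by(fdm, .data$contig),
                        fdm = mean(.data$fdm, na.rm = TRUE),
                        .groups = "drop")
  m <- dplyr::inner_join(m, contig_lengths, by = "contig")
  if (nrow(m) < 3 || sd(m$fdm) == 0 || sd(m$length) == 0)
    return(tibble::tibble(r = NA_real_, p = NA_real_,
                          n_contigs = nrow(m), flag = "undefined"))
  ct <- cor.test(m$fdm, m$length, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n_contigs = nrow(m), flag = NA_character_)
}

#' Fraction of site pairs violating the four-gamete condition
#'
#' Over all pairs of polymorphic sites in a window, the fraction whose
#' phased haplotypes display all four gametes (00, 01, 10, 11) - evidence
#' of recombination (or recurrent mutation).
#'
#' @param haplotypes Phased 0/1 matrix, haplotypes in rows.
#' @return Scalar fraction, or `NA` when fewer than 2 polymorphic sites.
#' @export
four_gamete_fraction <- function(haplotypes) {
  H <- haplotypes[, colSums(haplotypes, na.rm = TRUE) > 0 &
                    colSums(haplotypes, na.rm = TRUE) <
                      colSums(!is.na(haplotypes)), drop = FALSE]
  S <- ncol(H)
  if (S < 2) return(NA_real_)
  H[is.na(H)] <- 0  # complete phased data expected; guard only
  A11 <- crossprod(H)
  A10 <- crossprod(H, 1 - H)
  A01 <- t(A10)
  A00 <- crossprod(1 - H)
  viol <- A11 > 0 & A10 > 0 & A01 > 0 & A00 > 0
  sum(viol[upper.tri(viol)]) / (S * (S - 1) / 2)
}

#' Windowed four-gamete fractions along the genome
#'
#' @param geno A `pop_genotypes`.
#' @param window_size Window width in bp (default 10,000).
#' @return Tibble: `contig`, `start`, `end`, `n_snps`, `fraction`.
#' @export
four_gamete_windows <- function(geno, window_size = 10000) {
  win_start <- ((geno$sites$pos - 1) %/% window_size) * window_size + 1
  key <- paste(geno$sites$contig, win_start)
  out <- list()
  for (kk in unique(key)) {
    idx <- which(key == kk)
    out[[length(out) + 1]] <- tibble::tibble(
      contig = geno$sites$contig[idx[1]],
      start = win_start[idx[1]],
      end = win_start[idx[1]] + window_size - 1,
      n_snps = length(idx),
      fraction = four_gamete_fraction(
        geno$haplotypes[, idx, drop = FALSE]))
  }
  dplyr::bind_rows(out)
}

#' Exact Hardy-Weinberg test p-value
#'
#' Exact two-sided test for a biallelic site from diploid genotype counts
#' (sum of probabilities of heterozygote counts no more likely than the
#' observed one, conditional on the allele counts).
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalised log-probabilities of each heterozygote count
  lp <- vapply(hets, function(h) {
    na <- (rare - h) / 2
    nb <- (2 * n - rare - h) / 2
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[p <= p[match(n_ab, hets)] + 1e-12])
}

#' Hardy-Weinberg filtering of sites
#'
#' Removes a site when the exact HWE p-value falls below `alpha` in any
#' tested population; sites on the designated barrier contig are exempt
#' (mirroring the exclusion of the chr18 colour locus from HWE pruning).
#'
#' @param geno A `pop_genotypes`.
#' @param alpha Significance threshold (default 1e-4).
#' @param barrier_contig Contig name exempt from removal (optional).
#' @param pops Populations to test (default: all).
#' @return A list: `retained` (site indices), `removed` (tibble `site`,
#'   `contig`, `pos`, `population`, `p`).
#' @export
hwe_filter <- function(geno, alpha = 1e-4, barrier_contig = NULL,
                       pops = NULL) {
  if (is.null(pops)) pops <- unique(geno$pop)
  H <- geno$haplotypes
  removed <- list()
  bad <- rep(FALSE, nrow(geno$sites))
  for (p in pops) {
    rows <- which(geno$pop == p)
    a1 <- H[rows[seq(1, length(rows), 2)], , drop = FALSE]
    a2 <- H[rows[seq(2, length(rows), 2)], , drop = FALSE]
    gsum <- a1 + a2
    for (s in seq_len(ncol(H))) {
      g <- gsum[, s]
      g <- g[!is.na(g)]
      pv <- hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
      if (pv < alpha) {
        bad[s] <- TRUE
        removed[[length(removed) + 1]] <- tibble::tibble(
          site = s, contig = geno$sites$contig[s],
          pos = geno$sites$pos[s], population = p, p = pv)
      }
    }
  }
  if (!is.null(barrier_contig))
    bad[geno$sites$contig == barrier_contig] <- FALSE
  rem <- dplyr::bind_rows(removed)
  if (nrow(rem) > 0 && !is.null(barrier_contig))
    rem <- rem[rem$contig != barrier_contig, , drop = FALSE]
  list(retained = which(!bad), removed = rem)
}

#' Tajima's D
#'
#' Standardised difference between the diversity-based and
#' segregating-sites-based estimates of theta, with the standard
#' normalising constants.  Sites with missing calls in the population are
#' dropped (complete-case).
#'
#' @param geno A `pop_genotypes` or a 0/1 haplotype matrix.
#' @param pop Population label (when `geno` is a `pop_genotypes`).
#' @return Tajima's D, or `NA` when there are no segregating sites or
#'   fewer than 3 sequences.
#' @export
tajimas_d <- function(geno, pop = NULL) {
  H <- if (inherits(geno, "pop_genotypes")) {
    if (is.null(pop)) stop("`pop` is required", call. = FALSE)
    geno$haplotypes[geno$pop == pop, , drop = FALSE]
  } else geno
  H <- H[, colSums(is.na(H)) == 0, drop = FALSE]
  n <- nrow(H)
  if (n < 3) return(NA_real_)
  cc <- colSums(H)
  seg <- cc > 0 & cc < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k <- sum(2 * cc[seg] * (n - cc[seg])) / (n * (n - 1))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
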