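# Compile a demographic_model into the piecewise-constant engine form the
# C++ simulator consumes: times in generations, per-segment sizes/growth,
# backward migration matrices, and merge lists at segment boundaries.

compile_model <- function(model, samples = NULL) {
  cfg <- model$config
  pops <- model$populations
  np <- nrow(pops)
  name <- pops$name
  idx <- setNames(seq_len(np) - 1L, name)  # 0-based for C++

  if (is.null(samples)) {
    samples <- setNames(2L * pops$n_diploid_samples, name)
  } else {
    bad <- setdiff(names(samples), name)
    if (length(bad) > 0)
      stop("samples reference unknown population(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    full <- setNames(rep(0L, np), name)
    full[names(samples)] <- as.integer(samples)
    samples <- full
  }
  if (sum(samples) < 2)
    stop("at least 2 haploid samples are required", call. = FALSE)

  g_of <- function(yr) yr / cfg$generation_time
  iv <- pop_intervals(model)
  alive_from <- setNames(g_of(iv$t_from), iv$name)
  alive_to <- setNames(g_of(iv$t_to), iv$name)

  tegr <- setNames(g_of(pops$growth_start_time), name)
  gr <- setNames(pops$growth_rate, name)
  ne <- setNames(pops$ne_present, name)

  brk <- c(0, g_of(model$splits$time),
           tegr[gr > 0 & tegr > 0],
           g_of(model$migration$start_time), g_of(model$migration$end_time))
  brk <- sort(unique(brk[is.finite(brk)]))
  nseg <- length(brk)

  N <- matrix(1, nseg, np)
  G <- matrix(0, nseg, np)
  ACT <- matrix(FALSE, nseg, np)
  for (p in seq_len(np)) {
    nm <- name[p]
    for (s in seq_len(nseg)) {
      t0 <- brk[s]
      ACT[s, p] <- t0 >= alive_from[nm] - 1e-12 && t0 < alive_to[nm] - 1e-12
      if (gr[nm] > 0 && tegr[nm] > 0) {
        if (t0 < tegr[nm] - 1e-12) {
          N[s, p] <- ne[nm] * exp(-gr[nm] * t0)
          G[s, p] <- gr[nm]
        } else {
          N[s, p] <- ne[nm] * exp(-gr[nm] * tegr[nm])
          G[s, p] <- 0
        }
      } else {
        N[s, p] <- ne[nm]
      }
    }
  }

  mig <- lapply(seq_len(nseg), function(s) matrix(0, np, np))
  for (i in seq_len(nrow(model$migration))) {
    m <- model$migration[i, ]
    a <- g_of(m$start_time); b <- g_of(m$end_time)
    di <- idx[[m$donor]] + 1L; ri <- idx[[m$recipient]] + 1L
    for (s in seq_len(nseg)) {
      t0 <- brk[s]
      t1 <- if (s < nseg) brk[s + 1] else Inf
      if (t0 >= a - 1e-12 && t1 <= b + 1e-12) {
        # backward: a lineage in the recipient moves to the donor
        mig[[s]][ri, di] <- mig[[s]][ri, di] + m$rate
      }
    }
  }

  merges <- lapply(seq_len(nseg), function(s) {
    matrix(integer(), nrow = 2, ncol = 0)
  })
  for (i in seq_len(nrow(model$splits))) {
    s <- which(abs(brk - g_of(model$splits$time[i])) < 1e-9)
    stopifnot(length(s) == 1)
    merges[[s]] <- cbind(merges[[s]],
                         c(idx[[model$splits$derived_pop[i]]],
                           idx[[model$splits$ancestral_pop[i]]]))
  }

  list(n_pop = np, samples = unname(samples), pop_names = name,
       breaks = brk, N = N, g = G, active = ACT, mig = mig,
       merges = merges, mutation_rate = cfg$mutation_rate,
       generation_time = cfg$generation_time)
}
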