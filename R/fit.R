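# Composite-likelihood model fitting on folded joint SFS of the six
# population pairs: observed-data simulation, profile likelihood, cyclic
# conditional maximisation (ECM-style golden-section line searches with
# common random numbers), AIC comparison, parametric bootstrap.

scenario_builder <- function(scenario) {
  switch(scenario,
         gws = build_gws_model,
         lsi = build_lsi_model,
         stop("unknown scenario '", scenario, "'", call. = FALSE))
}

sfs_panel_pairs <- function(pops = c("SPA", "EURw", "EURns", "IRQ")) {
  cmb <- utils::combn(pops, 2)
  lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
}

#' Simulate an observed folded joint-SFS set
#'
#' Generates polymorphic sites (Poisson mutations on simulated genealogies,
#' or a finite-sites HKY layer) for `n_loci` independent loci and tabulates
#' the folded joint SFS of every population pair.
#'
#' @param model A `demographic_model` with sampled populations.
#' @param n_loci Number of independent loci.
#' @param locus_length Locus length in bp.
#' @param seed Integer seed.
#' @param pairs List of population-name pairs (default: all pairs of
#'   sampled populations).
#' @param mutation_model `"infinite_sites"` or `"hky"`.
#' @return A named list of `jsfs` objects.
#' @export
sim_observed_jsfs <- function(model, n_loci, locus_length = 2000, seed = 1L,
                              pairs = NULL,
                              mutation_model = c("infinite_sites", "hky")) {
  mutation_model <- match.arg(mutation_model)
  es <- compile_model(model)
  if (is.null(pairs)) {
    sampled <- es$pop_names[es$samples > 0]
    pairs <- sfs_panel_pairs(sampled)
  }
  if (mutation_model == "infinite_sites") {
    pidx <- vapply(pairs, function(pr) match(pr, es$pop_names) - 1L,
                   integer(2))
    mats <- cpp_sim_jsfs(es, as.integer(n_loci), locus_length,
                         es$mutation_rate, t(pidx), as.double(seed), TRUE)
    out <- lapply(seq_along(pairs), function(k) {
      f <- fold_matrix(mats[[k]])
      new_jsfs(f, pairs[[k]], nrow(f) - 1L, ncol(f) - 1L)
    })
    names(out) <- vapply(pairs, paste, character(1), collapse = "-")
    return(out)
  }
  # finite-sites: mutate each genealogy under HKY and count biallelic sites
  gl <- cpp_sim_genealogies(es, as.integer(n_loci), as.double(seed))
  pop_of <- rep(es$pop_names, es$samples)
  mats <- lapply(pairs, function(pr)
    matrix(0, sum(pop_of == pr[1]) + 1, sum(pop_of == pr[2]) + 1))
  for (l in seq_along(gl)) {
    g <- gl[[l]]
    res <- cpp_mutate_hky(g$parent, g$time, g$n_leaves, locus_length,
                          es$mutation_rate, 0.5,
                          as.double(locus_seed_r(seed, l)))
    if (length(res$positions) == 0) next
    A <- res$alleles
    for (s in seq_len(ncol(A))) {
      al <- A[, s]
      tab <- sort(unique(al))
      if (length(tab) != 2) next  # skip non-biallelic
      der <- al != res$ancestral[s]
      if (!any(der) || all(der)) der <- al == tab[2]
      for (k in seq_along(pairs)) {
        i <- sum(der[pop_of == pairs[[k]][1]])
        j <- sum(der[pop_of == pairs[[k]][2]])
        mats[[k]][i + 1, j + 1] <- mats[[k]][i + 1, j + 1] + 1
      }
    }
  }
  out <- lapply(seq_along(pairs), function(k) {
    f <- fold_matrix(mats[[k]])
    new_jsfs(f, pairs[[k]], nrow(f) - 1L, ncol(f) - 1L)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "-")
  out
}

# R-side mirror of the C++ per-locus counter seeding (any deterministic
# derivation works here; reproducibility is all that matters)
locus_seed_r <- function(master, i) {
  (as.double(master) * 48271 + i * 1103) %% 2147483647
}

#' Composite log10 likelihood of a model given observed joint SFS
#'
#' Simulates the expected folded SFS for every observed pair (branch-length
#' accumulation over `n_sim_loci` loci) and sums the per-pair multinomial
#' composite log10 likelihoods.
#'
#' @param model A `demographic_model`.
#' @param obs Named list of observed `jsfs` objects.
#' @param n_sim_loci Simulated loci per likelihood evaluation.
#' @param locus_length Locus length in bp.
#' @param seed Integer seed (reuse for common random numbers).
#' @param p_floor Probability floor for unpopulated cells.
#' @return Scalar log10 composite likelihood.
#' @export
model_loglik <- function(model, obs, n_sim_loci = 2000, locus_length = 2000,
                         seed = 1L, p_floor = 1e-8) {
  pairs <- lapply(obs, function(o) o$pops)
  ex <- expected_jsfs_set(model, pairs, n_sim_loci, locus_length, seed,
                          poisson = FALSE, p_floor = p_floor)
  sum(vapply(seq_along(obs), function(k)
    composite_loglik(obs[[k]], ex[[k]]), numeric(1)))
}

#' Single-parameter profile of the composite likelihood
#'
#' Holds all parameters at `params` except `free`, which sweeps `grid`;
#' every evaluation re-simulates the expected SFS with common random
#' numbers (the same seed), so the profile is smooth in the parameter.
#'
#' @param obs Named list of observed `jsfs`.
#' @param scenario `"gws"` or `"lsi"` (or a model-builder function).
#' @param params Full named parameter list (the generating values).
#' @param free Name of the profiled parameter.
#' @param grid Numeric vector of values to evaluate.
#' @param n_sim_loci Simulated loci per grid point.
#' @param locus_length Locus length in bp.
#' @param seed Integer seed (shared across grid points).
#' @return A tibble of class `profile_lik` with columns `value`,
#'   `log10_lik`; attributes `free`, `maximiser`.
#' @export
profile_likelihood <- function(obs, scenario, params, free, grid,
                               n_sim_loci = 2000, locus_length = 2000,
                               seed = 1L) {
  builder <- if (is.function(scenario)) scenario
             else scenario_builder(scenario)
  ll <- vapply(grid, function(v) {
    p <- params
    p[[free]] <- v
    # grid points that violate the scenario topology (e.g. a split younger
    # than the fixed contact time) are impossible models: zero likelihood
    m <- tryCatch(builder(p), error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    model_loglik(m, obs, n_sim_loci, locus_length, seed)
  }, numeric(1))
  out <- tibble::tibble(value = grid, log10_lik = ll)
  class(out) <- c("profile_lik", class(out))
  attr(out, "free") <- free
  attr(out, "maximiser") <- grid[which.max(ll)]
  out
}

# golden-section maximisation of f on [lo, hi]
golden_max <- function(f, lo, hi, n_iter = 10) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(n_iter)) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  if (f1 > f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

is_log_scale_param <- function(name) grepl("^(m_|ne_|gr_)", name)

#' Fit a demographic model by cyclic conditional maximisation
#'
#' ECM-style optimisation of the composite likelihood: each cycle updates
#' one free parameter at a time by a golden-section line search within its
#' range, re-simulating the expected folded SFS per evaluation with common
#' random numbers.  Rates and sizes are searched on a log scale, times on a
#' linear scale.  Multiple starts are supported; the best final likelihood
#' wins.
#'
#' @param obs Named list of observed `jsfs`.
#' @param scenario `"gws"` or `"lsi"` (or a builder function).
#' @param params_init Full named parameter list used as the first start.
#' @param free Character vector of free parameter names (>= 1 unless the
#'   fixed model's likelihood is wanted).
#' @param lower,upper Named numeric bounds for the free parameters.
#' @param n_cycles Conditional-maximisation cycles per start.
#' @param n_sim_loci Simulated loci per likelihood evaluation.
#' @param locus_length Locus length in bp.
#' @param seed Integer seed (controls CRN streams and extra starts).
#' @param n_starts Number of starts (start 1 = `params_init`, later starts
#'   drawn uniformly within the ranges).
#' @param golden_iter Golden-section iterations per parameter update.
#' @param final_sim_loci Loci for the final likelihood evaluation (defaults
#'   to `max(4 * n_sim_loci, 2000)`), evaluated with a common seed so fits
#'   of competing models are comparable.
#' @return An object of class `demog_fit`.
#' @export
fit_model <- function(obs, scenario, params_init, free,
                      lower = NULL, upper = NULL, n_cycles = 2,
                      n_sim_loci = 500, locus_length = 2000, seed = 1L,
                      n_starts = 1, golden_iter = 8,
                      final_sim_loci = NULL) {
  builder <- if (is.function(scenario)) scenario
             else scenario_builder(scenario)
  scen_name <- if (is.function(scenario)) "custom" else scenario
  if (is.null(final_sim_loci)) final_sim_loci <- max(4 * n_sim_loci, 2000)
  if (length(free) == 0) {
    ll <- model_loglik(builder(params_init), obs, final_sim_loci,
                       locus_length, seed)
    return(new_demog_fit(scen_name, params_init, ll, 0L, tibble::tibble(),
                         converged = TRUE))
  }
  if (is.null(lower) || is.null(upper))
    stop("`lower` and `upper` ranges are required for free parameters",
         call. = FALSE)
  if (!all(free %in% names(lower)) || !all(free %in% names(upper)))
    stop("ranges must cover every free parameter", call. = FALSE)
  if (any(!is.finite(unlist(lower[free]))) ||
      any(!is.finite(unlist(upper[free]))))
    stop("parameter ranges must be finite", call. = FALSE)

  set.seed(as.integer(seed %% .Machine$integer.max))
  starts <- list(params_init)
  if (n_starts > 1) for (s in 2:n_starts) {
    p <- params_init
    for (f in free) {
      if (is_log_scale_param(f))
        p[[f]] <- exp(runif(1, log(lower[[f]]), log(upper[[f]])))
      else p[[f]] <- runif(1, lower[[f]], upper[[f]])
    }
    starts[[s]] <- p
  }

  best <- NULL
  trace <- list()
  for (s in seq_along(starts)) {
    p <- starts[[s]]
    crn_seed <- as.double(seed) * 1000 + s
    evalf <- function(pp) {
      # proposals violating the scenario topology are impossible models
      m <- tryCatch(builder(pp), error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      ll <- model_loglik(m, obs, n_sim_loci, locus_length, crn_seed)
      if (is.nan(ll)) stop("optimizer error: NaN likelihood",
                           call. = FALSE)
      ll
    }
    ll_cur <- evalf(p)
    for (cyc in seq_len(n_cycles)) {
      for (f in free) {
        lg <- is_log_scale_param(f)
        obj <- function(x) {
          pp <- p
          pp[[f]] <- if (lg) exp(x) else x
          evalf(pp)
        }
        rng <- if (lg) log(c(lower[[f]], upper[[f]]))
               else c(lower[[f]], upper[[f]])
        opt <- golden_max(obj, rng[1], rng[2], golden_iter)
        cand <- if (lg) exp(opt$x) else opt$x
        if (opt$f >= ll_cur) {
          p[[f]] <- cand
          ll_cur <- opt$f
        }
        trace[[length(trace) + 1]] <-
          tibble::tibble(start = s, cycle = cyc, parameter = f,
                         value = p[[f]], log10_lik = ll_cur)
      }
    }
    ll_final <- model_loglik(builder(p), obs, final_sim_loci, locus_length,
                             as.double(seed) * 7919)
    if (is.null(best) || ll_final > best$ll) {
      best <- list(p = p, ll = ll_final, start = s)
    }
  }
  new_demog_fit(scen_name, best$p, best$ll, length(free),
                dplyr::bind_rows(trace), converged = TRUE,
                best_start = best$start)
}

new_demog_fit <- function(scenario, params, log10_lik, k, trace,
                          converged = TRUE, best_start = 1L) {
  structure(list(scenario = scenario, params = params,
                 log10_lik = log10_lik, k = k,
                 aic = aic(log10_lik, k), trace = trace,
                 converged = converged, best_start = best_start),
            class = "demog_fit")
}

#' @export
print.demog_fit <- function(x, ...) {
  cat("<demog_fit> scenario ", x$scenario, ": log10 L = ",
      format(x$log10_lik), ", k = ", x$k, ", AIC = ", format(x$aic),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_model Tidy the fitted parameters.
#' @param x A `demog_fit`.
#' @param ... Unused.
#' @export
tidy.demog_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' @describeIn fit_model One-row model summary (log10 L, k, AIC).
#' @export
glance.demog_fit <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, log10_lik = x$log10_lik, k = x$k,
                 AIC = x$aic, converged = x$converged)
}

#' Compare fitted models by AIC
#'
#' @param ... `demog_fit` objects (named or not).
#' @return A tibble sorted by AIC with a `winner` attribute (lowest AIC).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab <- dplyr::arrange(tab, .data$AIC)
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  attr(tab, "winner") <- tab$scenario[1]
  tab
}

#' Parametric bootstrap of a fitted model
#'
#' Simulates `n_reps` observed joint-SFS sets at the point estimate and
#' refits each, initialising at the point estimate.  Replicate failures are
#' recorded and excluded.
#'
#' @param fit A `demog_fit`.
#' @param scenario `"gws"` or `"lsi"`.
#' @param free Free parameters to re-estimate.
#' @param lower,upper Ranges, as in [fit_model()].
#' @param n_reps Bootstrap replicates (the full-scale analysis uses 100).
#' @param n_loci Loci per simulated replicate (full scale: 636,281 loci of
#'   1000 bp covering the scaled neutral genome).
#' @param locus_length Locus length in bp.
#' @param mutation_model `"infinite_sites"` or `"hky"`.
#' @param n_cycles,n_sim_loci,golden_iter Refit settings.
#' @param seed Integer seed.
#' @return A `bootstrap_result`: replicate estimates, bias-corrected point
#'   estimates and quantile intervals.
#' @export
parametric_bootstrap <- function(fit, scenario, free, lower, upper,
                                 n_reps = 100, n_loci = 636281,
                                 locus_length = 1000,
                                 mutation_model = "infinite_sites",
                                 n_cycles = 1, n_sim_loci = 300,
                                 golden_iter = 6, seed = 1L) {
  builder <- scenario_builder(scenario)
  model <- builder(fit$params)
  reps <- list()
  failures <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- as.double(seed) * 131071 + r
    obs_r <- sim_observed_jsfs(model, n_loci, locus_length, rep_seed,
                               mutation_model = mutation_model)
    f <- tryCatch(
      fit_model(obs_r, scenario, fit$params, free, lower, upper,
                n_cycles = n_cycles, n_sim_loci = n_sim_loci,
                locus_length = locus_length, seed = rep_seed + 0.5,
                golden_iter = golden_iter),
      error = function(e) NULL)
    if (is.null(f)) { failures <- failures + 1L; next }
    reps[[length(reps) + 1]] <-
      tibble::as_tibble(f$params[free])
  }
  replicates <- dplyr::bind_rows(reps)
  point <- unlist(fit$params[free])
  bc <- bias_correct(point, replicates)
  structure(list(replicates = replicates, point = point,
                 bias_corrected = bc$corrected, quantiles = bc$quantiles,
                 n_failed = failures, n_reps = n_reps),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", nrow(x$replicates), " replicates (",
      x$n_failed, " failed)\n", sep = "")
  print(x$bias_corrected)
  invisible(x)
}

#' Bootstrap bias correction and quantiles
#'
#' `corrected = 2 * point - mean(replicates)`; quantiles at the default
#' probabilities of [stats::quantile()] plus 2.5% / 97.5%.
#'
#' @param point Named numeric point estimates.
#' @param replicates Data frame of replicate estimates (columns match
#'   `point` names).
#' @return A list with `corrected` (named numeric) and `quantiles` (tibble).
#' @export
bias_correct <- function(point, replicates) {
  if (nrow(replicates) < 1)
    stop("at least one replicate is required", call. = FALSE)
  nm <- names(point)
  mu <- vapply(nm, function(f) mean(replicates[[f]]), numeric(1))
  corrected <- 2 * point - mu
  probs <- sort(unique(c(0, 0.025, 0.25, 0.5, 0.75, 0.975, 1)))
  q <- lapply(nm, function(f)
    tibble::tibble(parameter = f, prob = probs,
                   value = unname(quantile(replicates[[f]], probs))))
  list(corrected = corrected, quantiles = dplyr::bind_rows(q))
}
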