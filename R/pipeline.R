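# End-to-end orchestration: generate -> stats -> SFS -> fit both models ->
# AIC comparison -> topology-weighting comparison, with a machine-readable
# report.

default_run_config <- function() {
  list(
    scenario = "gws",
    seed = 1L,
    out_dir = NULL,
    generate = list(params = list(),
                    layout = list(n_contigs = 6L, loci_per_contig = 40L,
                                  locus_length = 2000L,
                                  barrier_contig = 6L, barrier_loci = 16L)),
    stats = list(window_size = 50000L),
    fit = list(free = c("t_anc", "t_eurns", "t_eurw", "t_contact",
                        "m_eurns_eurw"),
               n_cycles = 1L, n_sim_loci = 400L, n_starts = 1L,
               golden_iter = 6L, locus_length = 2000L),
    bootstrap = list(enabled = FALSE, n_reps = 10L, n_loci = 2000L,
                     locus_length = 1000L),
    twisst = list(n_trees = 200L, taxa = c("SPA", "EURw", "EURns"),
                  k = 20L, n_iter = 2000L, locus_length = 2500L))
}

#' Run the full model-comparison pipeline
#'
#' Generates a synthetic dataset under the configured scenario, computes
#' windowed statistics, builds the folded joint SFS of all population
#' pairs, fits both competing demographic models, compares them by AIC,
#' and contrasts topology-weighting ternary distributions of the observed
#' data against tree sets simulated under each fitted model.  The whole
#' chain is deterministic given the master seed.
#'
#' @param config A configuration list, or a path to a JSON file with the
#'   same structure; missing entries fall back to desk-scale defaults (see
#'   `crowdemog:::default_run_config`).
#' @return A `run_report` (list): config echo, seeds, per-model estimates,
#'   AIC table and winner, topology-weighting L1 distances, artifact
#'   paths.  Also written as `report.json` in the output directory,
#'   alongside a human-readable log.  On a stage failure a partial report
#'   with the stage error recorded is written before the error is
#'   re-raised.
#' @export
run_comparison <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_run_config(), config,
                           keep.null = TRUE)
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("crowdemog_run_")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S"), " ",
                                   ..., "\n"),
                            file = log_path, append = TRUE)
  report <- list(config = cfg, seed = cfg$seed, stages = list(),
                 artifacts = list())
  finish <- function(report) {
    jsonlite::write_json(report,
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    report
  }
  run_stage <- function(name, expr) {
    logf("stage ", name, " started")
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(out))
      finish(report)
      stop("stage '", name, "' failed: ", conditionMessage(out),
           call. = FALSE)
    }
    report$stages[[name]] <<- list(status = "ok")
    logf("stage ", name, " done")
    out
  }

  ds <- run_stage("generate", {
    generate_dataset(cfg$scenario, cfg$generate$params,
                     cfg$generate$layout, cfg$seed,
                     dir = file.path(cfg$out_dir, "data"))
  })
  report$artifacts$vcf <- ds$vcf
  report$artifacts$truth <- ds$truth_file
  report$artifacts$window_stats <- file.path(cfg$out_dir,
                                             "window_stats.tsv")

  ws <- run_stage("stats", {
    w <- window_stats(ds$geno, cfg$stats$window_size)
    pth <- file.path(cfg$out_dir, "window_stats.tsv")
    utils::write.table(w, pth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    w
  })

  obs <- run_stage("sfs", {
    pops <- unique(ds$geno$pop)
    prs <- sfs_panel_pairs(pops)
    o <- lapply(prs, function(pr)
      folded_jsfs(ds$geno, pr[1], pr[2]))
    names(o) <- vapply(prs, paste, character(1), collapse = "-")
    for (nm in names(o))
      write_jsfs_obs(o[[nm]], file.path(cfg$out_dir,
                                        paste0("jsfs_", nm, ".obs")))
    o
  })

  gen_params <- utils::modifyList(
    if (cfg$scenario == "gws") default_gws_params()
    else default_lsi_params(), cfg$generate$params)
  fits <- run_stage("fit", {
    lapply(setNames(c("gws", "lsi"), c("gws", "lsi")), function(sc) {
      init <- translate_params(gen_params, cfg$scenario, sc)
      free <- intersect(translate_free(cfg$fit$free, sc), names(init))
      rng <- default_fit_ranges(init, free)
      fit_model(obs, sc, init, free,
                rng$lower, rng$upper, n_cycles = cfg$fit$n_cycles,
                n_sim_loci = cfg$fit$n_sim_loci,
                locus_length = cfg$fit$locus_length,
                seed = cfg$seed + 17, n_starts = cfg$fit$n_starts,
                golden_iter = cfg$fit$golden_iter)
    })
  })
  aic_tab <- compare_models(fits$gws, fits$lsi)
  report$fits <- lapply(fits, function(f)
    list(params = f$params, log10_lik = f$log10_lik, k = f$k,
         aic = f$aic))
  report$aic_table <- as.data.frame(aic_tab)
  report$winner <- attr(aic_tab, "winner")
  logf("AIC winner: ", report$winner)

  if (isTRUE(cfg$bootstrap$enabled)) {
    bs <- run_stage("bootstrap", {
      win <- fits[[report$winner]]
      rng <- default_fit_ranges(win$params, cfg$fit$free)
      parametric_bootstrap(win, report$winner,
                           intersect(cfg$fit$free, names(win$params)),
                           rng$lower, rng$upper,
                           n_reps = cfg$bootstrap$n_reps,
                           n_loci = cfg$bootstrap$n_loci,
                           locus_length = cfg$bootstrap$locus_length,
                           n_cycles = 1, n_sim_loci = cfg$fit$n_sim_loci,
                           seed = cfg$seed + 29)
    })
    report$bootstrap <- list(bias_corrected = as.list(bs$bias_corrected),
                             n_failed = bs$n_failed)
  }

  tw <- run_stage("twisst", {
    twisst_comparison(ds, fits, cfg, obs_trees = NULL)
  })
  report$twisst <- tw
  logf("twisst L1: gws=", tw$L1_gws, " lsi=", tw$L1_lsi)

  report <- finish(report)
  class(report) <- "run_report"
  invisible(report)
}

# map the generating parameter names of one scenario onto the other
# (shared leaf/migration/growth names pass through; split times map by
# topological role)
translate_params <- function(params, from, to) {
  if (from == to) return(params)
  shared <- params[!grepl("^t_|^ne_anc_cc$|^ne_anc_wns$",
                          names(params))]
  if (to == "lsi") {
    c(shared, list(t_anc = params$t_anc, t_hc = params$t_eurns,
                   t_wns = max(params$t_eurw, params$t_contact * 1.01),
                   t_contact = params$t_contact,
                   ne_anc_wns = params$ne_anc_cc %||% 1e5))
  } else {
    c(shared, list(t_anc = params$t_anc, t_eurns = params$t_hc,
                   t_eurw = params$t_wns,
                   t_contact = min(params$t_contact,
                                   params$t_wns * 0.99),
                   ne_anc_cc = params$ne_anc_wns %||% 1e5))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# role-equivalent free-parameter names across the two scenarios, so both
# fits carry the same number of free parameters (k) in the AIC comparison
translate_free <- function(free, scenario) {
  if (scenario == "lsi") {
    free[free == "t_eurns"] <- "t_hc"
    free[free == "t_eurw"] <- "t_wns"
  } else {
    free[free == "t_hc"] <- "t_eurns"
    free[free == "t_wns"] <- "t_eurw"
  }
  unique(free)
}

default_fit_ranges <- function(params, free) {
  lower <- list(); upper <- list()
  for (f in free) {
    if (!f %in% names(params)) next
    v <- params[[f]]
    if (is_log_scale_param(f)) {
      lower[[f]] <- v / 10
      upper[[f]] <- min(v * 10, 0.99)
    } else {
      lower[[f]] <- v * 0.5
      upper[[f]] <- v * 1.5
    }
  }
  list(lower = lower, upper = upper)
}

twisst_comparison <- function(ds, fits, cfg, obs_trees = NULL) {
  taxa <- cfg$twisst$taxa
  n_trees <- cfg$twisst$n_trees
  if (is.null(obs_trees)) {
    # "observed" gene trees: simulated under the generating scenario at
    # the truth (a fresh seed), mirroring the role of the empirical trees
    gen_model <- scenario_builder(cfg$scenario)(
      utils::modifyList(
        if (cfg$scenario == "gws") default_gws_params()
        else default_lsi_params(), cfg$generate$params))
    obs_trees <- simulate_tree_set(gen_model, n_trees, cfg$seed + 101,
                                   outgroup = TRUE)
  }
  wt_obs <- topology_weight_table(obs_trees, taxa, outgroup = outgroup_tips(obs_trees[[1]]),
                                  n_iter = cfg$twisst$n_iter,
                                  seed = cfg$seed + 1)
  grid_obs <- ternary_bin(wt_obs, cfg$twisst$k)
  out <- list()
  for (sc in c("gws", "lsi")) {
    mdl <- scenario_builder(sc)(fits[[sc]]$params)
    tr <- simulate_tree_set(mdl, n_trees, cfg$seed + 202,
                            outgroup = TRUE)
    wt <- topology_weight_table(tr, taxa,
                                outgroup = outgroup_tips(tr[[1]]),
                                n_iter = cfg$twisst$n_iter,
                                seed = cfg$seed + 2)
    cmpr <- compare_ternary(grid_obs, ternary_bin(wt, cfg$twisst$k))
    out[[paste0("L1_", sc)]] <- attr(cmpr, "L1")
  }
  out$closer_model <- if (out$L1_gws <= out$L1_lsi) "gws" else "lsi"
  out
}

outgroup_tips <- function(tree) grep("^OUT_", tree$tip.label, value = TRUE)

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> scenario ", x$config$scenario, ", seed ", x$seed,
      "\n  AIC winner: ", x$winner, "\n", sep = "")
  if (!is.null(x$twisst))
    cat("  twisst L1 (gws/lsi): ", x$twisst$L1_gws, " / ",
        x$twisst$L1_lsi, "\n", sep = "")
  invisible(x)
}
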