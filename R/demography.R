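# Demographic histories: populations, splits, migration epochs, growth.
#
# Times are stored in YEARS before present and converted to continuous
# generations only at simulation time.  Migration rates are FORWARD-time
# donor -> recipient fractions per generation; the coalescent engine swaps
# indices to obtain backward lineage-movement rates.

#' Global configuration for demographic models
#'
#' Holds the per-site per-generation mutation rate and the generation time
#' used to convert years to generations.  The defaults are the values used
#' throughout the crow analyses: mu = 3.18e-9 and g = 5.79 years.
#'
#' @param mutation_rate Per-site per-generation mutation probability.
#' @param generation_time Generation time in years.
#' @param rng_seed Optional integer seed recorded with the model.
#' @return A list of class `global_config`.
#' @export
global_config <- function(mutation_rate = 3.18e-9, generation_time = 5.79,
                          rng_seed = NULL) {
  if (!is.numeric(mutation_rate) || mutation_rate <= 0)
    stop("`mutation_rate` must be > 0", call. = FALSE)
  if (!is.numeric(generation_time) || generation_time <= 0)
    stop("`generation_time` must be > 0", call. = FALSE)
  structure(list(mutation_rate = mutation_rate,
                 generation_time = generation_time,
                 rng_seed = rng_seed),
            class = "global_config")
}

#' Convert years before present to generations
#'
#' @param t Time in years (non-negative, vectorised).
#' @param config A [global_config()].
#' @return `t / generation_time`, a real number of generations.
#' @examples
#' years_to_generations(504000, global_config())
#' @export
years_to_generations <- function(t, config = global_config()) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  t / config$generation_time
}

#' Define a population
#'
#' @param name Population label.
#' @param n_diploid_samples Number of diploid individuals sampled.
#' @param ne_present Present-day diploid effective size.
#' @param growth_rate Per-generation exponential growth rate (0 = constant).
#'   Backward in time the size declines as
#'   `ne_present * exp(-growth_rate * generations(t))` until
#'   `growth_start_time`, and is constant earlier.
#' @param growth_start_time Years before present at which growth began.
#' @return A one-row tibble.
#' @export
population <- function(name, n_diploid_samples = 0, ne_present,
                       growth_rate = 0, growth_start_time = 0) {
  tibble::tibble(name = as.character(name),
                 n_diploid_samples = as.integer(n_diploid_samples),
                 ne_present = as.numeric(ne_present),
                 growth_rate = as.numeric(growth_rate),
                 growth_start_time = as.numeric(growth_start_time))
}

#' Assemble a demographic model
#'
#' @param name Model label.
#' @param populations Tibble of populations (rows from [population()]).
#' @param splits Tibble with columns `time` (years), `derived_pop`,
#'   `ancestral_pop`.  Backward in time the derived population's lineages
#'   merge into the ancestral population at `time`.
#' @param migration Tibble with columns `start_time`, `end_time` (years,
#'   backward axis, `start_time < end_time`, 0 = present), `donor`,
#'   `recipient`, `rate` (forward-time fraction per generation).
#' @param config A [global_config()].
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(name, populations, splits = empty_splits(),
                              migration = empty_migration(),
                              config = global_config()) {
  model <- structure(list(name = name,
                          populations = tibble::as_tibble(populations),
                          splits = tibble::as_tibble(splits),
                          migration = tibble::as_tibble(migration),
                          config = config),
                     class = "demographic_model")
  v <- validate_model(model)
  if (nrow(v) > 0)
    stop("invalid demographic model:\n",
         paste0("  - [", v$field, "] ", v$message, collapse = "\n"),
         call. = FALSE)
  model
}

#' @rdname demographic_model
#' @export
empty_splits <- function() {
  tibble::tibble(time = numeric(), derived_pop = character(),
                 ancestral_pop = character())
}

#' @rdname demographic_model
#' @export
empty_migration <- function() {
  tibble::tibble(start_time = numeric(), end_time = numeric(),
                 donor = character(), recipient = character(),
                 rate = numeric())
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> ", x$name, "\n", sep = "")
  cat("  populations: ", paste(x$populations$name, collapse = ", "), "\n")
  cat("  splits: ", nrow(x$splits), "; migration edges: ",
      nrow(x$migration), "\n", sep = "")
  invisible(x)
}

# Existence window of every population on the backward time axis.
# A sampled population lives from the present; an ancestral-only population
# (no samples, target of at least one split) comes alive at the earliest
# split feeding it.  Lifetimes end when the population merges away.
pop_intervals <- function(model) {
  pops <- model$populations$name
  sampled <- setNames(model$populations$n_diploid_samples > 0, pops)
  t_from <- setNames(rep(0, length(pops)), pops)
  t_to <- setNames(rep(Inf, length(pops)), pops)
  for (p in pops) {
    fed <- model$splits$time[model$splits$ancestral_pop == p]
    if (length(fed) > 0 && !sampled[p]) t_from[p] <- min(fed)
    away <- model$splits$time[model$splits$derived_pop == p]
    if (length(away) > 0) t_to[p] <- min(away)
  }
  tibble::tibble(name = pops, t_from = unname(t_from[pops]),
                 t_to = unname(t_to[pops]))
}

#' Validate a demographic model
#'
#' Checks all type invariants and returns violations instead of raising.
#'
#' @param model A `demographic_model` (possibly not yet validated).
#' @return A tibble with columns `field`, `rule`, `message`; zero rows iff
#'   the model is valid.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(field, rule, message)
    v[[length(v) + 1]] <<- tibble::tibble(field = field, rule = rule,
                                          message = message)
  cfg <- model$config
  if (cfg$mutation_rate <= 0)
    add("config.mutation_rate", "positive", "mutation_rate must be > 0")
  if (cfg$generation_time <= 0)
    add("config.generation_time", "positive", "generation_time must be > 0")
  pops <- model$populations
  if (anyDuplicated(pops$name))
    add("populations.name", "unique", "population names must be unique")
  for (i in seq_len(nrow(pops))) {
    p <- pops[i, ]
    if (p$ne_present <= 0)
      add(paste0("populations.", p$name, ".ne_present"), "positive",
          paste0("ne_present of ", p$name, " must be > 0"))
    if (p$n_diploid_samples < 0)
      add(paste0("populations.", p$name, ".n_diploid_samples"),
          "non-negative", "sample count must be >= 0")
    if (p$growth_rate < 0)
      add(paste0("populations.", p$name, ".growth_rate"), "non-negative",
          "growth_rate must be >= 0")
    if (p$growth_start_time < 0)
      add(paste0("populations.", p$name, ".growth_start_time"),
          "non-negative", "growth_start_time must be >= 0")
  }
  sp <- model$splits
  for (i in seq_len(nrow(sp))) {
    s <- sp[i, ]
    if (s$time <= 0)
      add(paste0("splits[", i, "].time"), "positive",
          "split time must be > 0")
    for (lab in c(s$derived_pop, s$ancestral_pop))
      if (!(lab %in% pops$name))
        add(paste0("splits[", i, "]"), "label-exists",
            paste0("unknown population '", lab, "'"))
  }
  if (any(duplicated(sp$derived_pop)))
    add("splits", "single-ancestor-path",
        "a population merges away more than once")
  # single rooted tree: following ancestor paths from every pop reaches one
  # root without cycles
  if (nrow(sp) > 0 && all(c(sp$derived_pop, sp$ancestral_pop) %in% pops$name) &&
      !any(duplicated(sp$derived_pop))) {
    anc <- setNames(sp$ancestral_pop, sp$derived_pop)
    roots <- character()
    for (p in pops$name) {
      seen <- character()
      q <- p
      while (q %in% names(anc)) {
        if (q %in% seen) {
          add("splits", "acyclic", "ancestor path contains a cycle")
          q <- NULL
          break
        }
        seen <- c(seen, q)
        q <- unname(anc[q])
      }
      if (!is.null(q)) roots <- union(roots, q)
    }
    if (length(roots) > 1)
      add("splits", "single-root",
          paste0("splits define ", length(roots), " roots: ",
                 paste(roots, collapse = ", ")))
    # merge into a population that has already merged away
    tmerge <- setNames(sp$time, sp$derived_pop)
    for (i in seq_len(nrow(sp))) {
      a <- sp$ancestral_pop[i]
      if (a %in% names(tmerge) && tmerge[a] <= sp$time[i])
        add(paste0("splits[", i, "]"), "ancestor-alive",
            paste0("ancestral population '", a,
                   "' has merged away before time ", sp$time[i]))
    }
  }
  mg <- model$migration
  iv <- tryCatch(pop_intervals(model), error = function(e) NULL)
  for (i in seq_len(nrow(mg))) {
    m <- mg[i, ]
    if (!is.na(m$rate) && (m$rate < 0 || m$rate >= 1))
      add(paste0("migration[", i, "].rate"), "rate-range",
          paste0("rate ", m$rate, " out of [0,1)"))
    if (m$start_time >= m$end_time)
      add(paste0("migration[", i, "]"), "interval",
          "start_time must be < end_time on the backward axis")
    for (lab in c(m$donor, m$recipient))
      if (!(lab %in% pops$name))
        add(paste0("migration[", i, "]"), "label-exists",
            paste0("unknown population '", lab, "'"))
    if (!is.null(iv) && all(c(m$donor, m$recipient) %in% iv$name)) {
      for (lab in c(m$donor, m$recipient)) {
        w <- iv[iv$name == lab, ]
        if (m$start_time < w$t_from - 1e-9 || m$end_time > w$t_to + 1e-9)
          add(paste0("migration[", i, "]"), "coexistence",
              paste0("epoch [", m$start_time, ", ", m$end_time,
                     "] extends outside the lifetime of '", lab, "'"))
      }
    }
  }
  # overlapping epochs for the same ordered pair
  if (nrow(mg) > 1) {
    key <- paste(mg$donor, mg$recipient, sep = "->")
    for (k in unique(key[duplicated(key)])) {
      rows <- mg[key == k, ]
      rows <- rows[order(rows$start_time), ]
      if (any(rows$end_time[-nrow(rows)] > rows$start_time[-1] + 1e-9))
        add("migration", "non-overlapping",
            paste0("epochs for ", k, " overlap"))
    }
  }
  if (length(v) == 0)
    tibble::tibble(field = character(), rule = character(),
                   message = character())
  else dplyr::bind_rows(v)
}

# ---------------------------------------------------------------------------
# The two competing scenarios.

default_gws_params <- function() {
  list(
    # divergence times, years before present
    t_anc = 504e3, t_eurns = 131e3, t_eurw = 34.5e3, t_contact = 20.0e3,
    # forward-time migration rates per generation, donor -> recipient
    m_spa_eurw = 3.16e-4, m_eurw_spa = 1.69e-4,
    m_irq_eurns = 5.68e-6, m_eurns_irq = 4.52e-5,
    m_eurns_eurw = 6.94e-4, m_eurw_eurns = 1.29e-4,
    # exponential growth of the expanding populations
    gr_eurw = 2.35e-4, tegr_eurw = 3.10e3,
    gr_eurns = 2.54e-4, tegr_eurns = 34.5e3,
    # present-day and ancestral diploid sizes (synthetic-work defaults,
    # not estimates)
    ne_spa = 5e4, ne_irq = 2e4, ne_eurw = 2e5, ne_eurns = 4e5,
    ne_anc_cc = 1e5, ne_anc_hc = 1e5, ne_anc = 1e5,
    # diploid sample sizes of the SFS panel
    n_spa = 15, n_eurw = 15, n_eurns = 15, n_irq = 5
  )
}

default_lsi_params <- function() {
  p <- default_gws_params()
  p$t_eurns <- NULL; p$t_eurw <- NULL
  p$ne_anc_cc <- NULL
  # EURw and EURns are sisters; their ancestor joins the Middle Eastern
  # lineage, and that lineage joins SPA at the root
  p <- c(p, list(t_hc = 131e3, t_wns = 34.5e3, ne_anc_wns = 1e5))
  p
}

check_params <- function(params, defaults, builder) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0)
    stop(builder, ": unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p <- utils::modifyList(defaults, params)
  miss <- names(p)[vapply(p, function(x) is.null(x) || is.na(x), logical(1))]
  if (length(miss) > 0)
    stop(builder, ": missing parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  p
}

#' Build the genome-wide swamping scenario
#'
#' Topology `((SPA,EURw),(EURns,IRQ))`: the Western European carrion crows
#' (EURw) split from the Iberian refugial lineage (SPA), the European hooded
#' crows (EURns) from the Middle Eastern refugial lineage (IRQ).  Migration
#' runs SPA<->EURw since the EURw split, IRQ<->EURns since the EURns split,
#' and EURw<->EURns since a secondary-contact time.  Defaults are the
#' fastsimcoal point estimates for times, migration and growth; effective
#' sizes default to synthetic-work values.
#'
#' @param params Named list overriding any defaults (see
#'   `crowdemog:::default_gws_params`).
#' @param config A [global_config()].
#' @return A validated `demographic_model`.
#' @examples
#' m <- build_gws_model()
#' nrow(m$splits)
#' @export
build_gws_model <- function(params = list(), config = global_config()) {
  p <- check_params(params, default_gws_params(), "build_gws_model")
  if (p$t_contact > p$t_eurw)
    stop("build_gws_model: secondary-contact time (", p$t_contact,
         ") is older than the EURw split (", p$t_eurw, ")", call. = FALSE)
  if (p$t_eurw > p$t_anc || p$t_eurns > p$t_anc)
    stop("build_gws_model: leaf split times exceed the root time",
         call. = FALSE)
  pops <- dplyr::bind_rows(
    population("SPA", p$n_spa, p$ne_spa),
    population("EURw", p$n_eurw, p$ne_eurw, p$gr_eurw, p$tegr_eurw),
    population("EURns", p$n_eurns, p$ne_eurns, p$gr_eurns, p$tegr_eurns),
    population("IRQ", p$n_irq, p$ne_irq),
    population("ANCcc", 0, p$ne_anc_cc),
    population("ANChc", 0, p$ne_anc_hc),
    population("ANC", 0, p$ne_anc))
  splits <- tibble::tibble(
    time = c(p$t_eurw, p$t_eurw, p$t_eurns, p$t_eurns, p$t_anc, p$t_anc),
    derived_pop = c("SPA", "EURw", "IRQ", "EURns", "ANCcc", "ANChc"),
    ancestral_pop = c("ANCcc", "ANCcc", "ANChc", "ANChc", "ANC", "ANC"))
  migration <- tibble::tibble(
    start_time = 0, end_time = c(p$t_eurw, p$t_eurw, p$t_eurns, p$t_eurns,
                                 p$t_contact, p$t_contact),
    donor = c("SPA", "EURw", "IRQ", "EURns", "EURns", "EURw"),
    recipient = c("EURw", "SPA", "EURns", "IRQ", "EURw", "EURns"),
    rate = c(p$m_spa_eurw, p$m_eurw_spa, p$m_irq_eurns, p$m_eurns_irq,
             p$m_eurns_eurw, p$m_eurw_eurns))
  m <- demographic_model("gws", pops, splits, migration, config)
  attr(m, "params") <- p
  attr(m, "scenario") <- "gws"
  m
}

#' Build the locus-specific introgression scenario
#'
#' Topology `((IRQ,(EURw,EURns)),SPA)`: EURw and EURns are sisters; only the
#' plumage locus is assumed to have crossed from the Iberian lineage.
#' Migration edges mirror the swamping scenario: EURw<->EURns since their
#' split, IRQ<->EURns since the hooded-lineage split, and SPA<->EURw since a
#' secondary-contact time representing the Pyrenean exchange.
#'
#' @inheritParams build_gws_model
#' @return A validated `demographic_model`.
#' @export
build_lsi_model <- function(params = list(), config = global_config()) {
  p <- check_params(params, default_lsi_params(), "build_lsi_model")
  if (p$t_contact > p$t_wns)
    stop("build_lsi_model: secondary-contact time (", p$t_contact,
         ") is older than the EURw-EURns split (", p$t_wns, ")",
         call. = FALSE)
  if (p$t_wns > p$t_hc || p$t_hc > p$t_anc)
    stop("build_lsi_model: split times must be ordered t_wns < t_hc < t_anc",
         call. = FALSE)
  pops <- dplyr::bind_rows(
    population("SPA", p$n_spa, p$ne_spa),
    population("EURw", p$n_eurw, p$ne_eurw, p$gr_eurw, p$tegr_eurw),
    population("EURns", p$n_eurns, p$ne_eurns, p$gr_eurns, p$tegr_eurns),
    population("IRQ", p$n_irq, p$ne_irq),
    population("ANCwns", 0, p$ne_anc_wns),
    population("ANChc", 0, p$ne_anc_hc),
    population("ANC", 0, p$ne_anc))
  splits <- tibble::tibble(
    time = c(p$t_wns, p$t_wns, p$t_hc, p$t_hc, p$t_anc, p$t_anc),
    derived_pop = c("EURw", "EURns", "ANCwns", "IRQ", "ANChc", "SPA"),
    ancestral_pop = c("ANCwns", "ANCwns", "ANChc", "ANChc", "ANC", "ANC"))
  migration <- tibble::tibble(
    start_time = 0, end_time = c(p$t_contact, p$t_contact, p$t_wns,
                                 p$t_wns, p$t_wns, p$t_wns),
    donor = c("SPA", "EURw", "IRQ", "EURns", "EURns", "EURw"),
    recipient = c("EURw", "SPA", "EURns", "IRQ", "EURw", "EURns"),
    rate = c(p$m_spa_eurw, p$m_eurw_spa, p$m_irq_eurns, p$m_eurns_irq,
             p$m_eurns_eurw, p$m_eurw_eurns))
  m <- demographic_model("lsi", pops, splits, migration, config)
  attr(m, "params") <- p
  attr(m, "scenario") <- "lsi"
  m
}

#' Attach an outgroup population to a model
#'
#' Adds an outgroup lineage that joins the root population at a deep
#' divergence time, as used for tree-based analyses and polarisation.
#'
#' @param model A `demographic_model` whose splits define a single root.
#' @param ne Outgroup diploid effective size (default 1e4).
#' @param time Divergence time in years (default 1e7).
#' @param n_diploid Diploid outgroup samples (default 1).
#' @param name Outgroup label.
#' @return A new validated `demographic_model` including the outgroup.
#' @export
attach_outgroup <- function(model, ne = 1e4, time = 1e7, n_diploid = 1,
                            name = "OUT") {
  root <- setdiff(model$populations$name, model$splits$derived_pop)
  if (length(root) != 1)
    stop("model must have a single root population", call. = FALSE)
  pops <- dplyr::bind_rows(model$populations, population(name, n_diploid, ne))
  splits <- dplyr::bind_rows(model$splits, tibble::tibble(
    time = time, derived_pop = name, ancestral_pop = root))
  m <- demographic_model(model$name, pops, splits, model$migration,
                         model$config)
  attr(m, "params") <- attr(model, "params")
  attr(m, "scenario") <- attr(model, "scenario")
  attr(m, "outgroup") <- name
  m
}
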