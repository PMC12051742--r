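# JSON round-trip for demographic models, and the shipped scenario presets.

#' Write / read a demographic model as JSON
#'
#' The document has blocks `config`, `populations`, `splits`,
#' `migration_epochs`; times in years, rates dimensionless.  Re-parsing a
#' written model yields an identical model field-by-field.
#'
#' @param model A `demographic_model`.
#' @param path File path.
#' @return `read_model_json` returns a validated `demographic_model`; the
#'   writer returns the path invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(name = model$name,
              config = list(mutation_rate = model$config$mutation_rate,
                            generation_time = model$config$generation_time,
                            rng_seed = model$config$rng_seed),
              populations = model$populations,
              splits = model$splits,
              migration_epochs = model$migration)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- global_config(doc$config$mutation_rate,
                       doc$config$generation_time,
                       doc$config$rng_seed)
  mg <- if (is.null(doc$migration_epochs) ||
            length(doc$migration_epochs) == 0) empty_migration()
        else tibble::as_tibble(doc$migration_epochs)
  demographic_model(doc$name, tibble::as_tibble(doc$populations),
                    tibble::as_tibble(doc$splits), mg, cfg)
}

#' Parameter presets for the two scenarios
#'
#' `"gws_fastsimcoal"` and `"lsi_fastsimcoal"` carry the fastsimcoal point
#' estimates for times, migration and growth; the `"*_jaatha"` variants the
#' Jaatha estimates.  Effective sizes are synthetic-work defaults in all
#' presets (the per-branch size estimates are not part of the preset).
#'
#' @param name Preset name.
#' @return A named parameter list for [build_gws_model()] /
#'   [build_lsi_model()].
#' @export
preset_params <- function(name = c("gws_fastsimcoal", "gws_jaatha",
                                   "lsi_fastsimcoal", "lsi_jaatha")) {
  name <- match.arg(name)
  jaatha_overrides <- list(
    m_spa_eurw = 9.70e-5, m_eurw_spa = 9.52e-5,
    m_irq_eurns = 8.82e-6, m_eurns_irq = 4.41e-5,
    m_eurns_eurw = 2.42e-4, m_eurw_eurns = 9.32e-5,
    gr_eurw = 3.74e-5, tegr_eurw = 28e3,
    gr_eurns = 8.74e-5, tegr_eurns = 17.8e3)
  switch(name,
    gws_fastsimcoal = list(),
    gws_jaatha = c(list(t_anc = 428e3, t_eurns = 107e3, t_eurw = 31.2e3,
                        t_contact = 30.6e3), jaatha_overrides),
    lsi_fastsimcoal = list(),
    lsi_jaatha = c(list(t_anc = 428e3, t_hc = 107e3, t_wns = 31.2e3,
                        t_contact = 30.6e3), jaatha_overrides))
}

#' Load a shipped model preset
#'
#' Reads one of the model JSON documents installed under
#' `extdata/models/`.
#'
#' @param name Preset name (see [preset_params()]).
#' @return A validated `demographic_model`.
#' @export
model_preset <- function(name = c("gws_fastsimcoal", "gws_jaatha",
                                  "lsi_fastsimcoal", "lsi_jaatha")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "crowdemog", mustWork = TRUE)
  read_model_json(path)
}
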