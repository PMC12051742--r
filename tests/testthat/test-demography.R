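test_that("the swamping scenario builds the ((SPA,EURw),(EURns,IRQ)) history", {
  m <- build_gws_model()
  expect_s3_class(m, "demographic_model")
  leaves <- m$populations$name[m$populations$n_diploid_samples > 0]
  expect_setequal(leaves, c("SPA", "EURw", "EURns", "IRQ"))
  expect_equal(sort(unique(m$splits$time)), c(34.5e3, 131e3, 504e3))
  # ancestor paths encode the topology
  anc <- setNames(m$splits$ancestral_pop, m$splits$derived_pop)
  path <- function(p) { out <- p; while (p %in% names(anc)) { p <- anc[[p]]; out <- c(out, p) }; out }
  expect_true("ANCcc" %in% path("SPA") && "ANCcc" %in% path("EURw"))
  expect_true("ANChc" %in% path("IRQ") && "ANChc" %in% path("EURns"))
  expect_false("ANCcc" %in% path("EURns"))
})

test_that("the locus-specific-introgression scenario differs only in topology", {
  g <- build_gws_model()
  l <- build_lsi_model()
  anc <- setNames(l$splits$ancestral_pop, l$splits$derived_pop)
  path <- function(p) { out <- p; while (p %in% names(anc)) { p <- anc[[p]]; out <- c(out, p) }; out }
  expect_true("ANCwns" %in% path("EURw") && "ANCwns" %in% path("EURns"))
  expect_false("ANCwns" %in% path("SPA"))
  # identical sample configuration
  gs <- g$populations[g$populations$n_diploid_samples > 0,
                      c("name", "n_diploid_samples")]
  ls <- l$populations[l$populations$n_diploid_samples > 0,
                      c("name", "n_diploid_samples")]
  expect_equal(gs, ls)
  expect_equal(g$populations$n_diploid_samples[match(
    c("SPA", "EURw", "EURns", "IRQ"), g$populations$name)],
    c(15L, 15L, 15L, 5L))
})

test_that("degenerate zero-migration models are valid strict-isolation models", {
  zero <- list(m_spa_eurw = 0, m_eurw_spa = 0, m_irq_eurns = 0,
               m_eurns_irq = 0, m_eurns_eurw = 0, m_eurw_eurns = 0)
  expect_s3_class(build_gws_model(zero), "demographic_model")
  expect_s3_class(build_lsi_model(zero), "demographic_model")
})

test_that("configuration errors name the offending parameter", {
  expect_error(build_gws_model(list(t_anc = NA)), "t_anc")
  expect_error(build_gws_model(list(nonsense = 1)), "nonsense")
  expect_error(build_gws_model(list(t_contact = 40e3)), "contact")
  expect_error(build_lsi_model(list(t_contact = 40e3)), "contact")
})

test_that("validate_model returns violations instead of raising", {
  m <- build_gws_model()
  expect_identical(nrow(validate_model(m)), 0L)
  bad <- m
  bad$migration$rate[5] <- 1.5
  v <- validate_model(bad)
  expect_true(any(v$rule == "rate-range"))
  expect_match(v$message[v$rule == "rate-range"], "1.5")
  bad2 <- m
  bad2$migration$end_time[5] <- 50e3  # contact epoch outlives EURw
  v2 <- validate_model(bad2)
  expect_true(any(v2$rule == "coexistence"))
  expect_match(v2$field[v2$rule == "coexistence"][1], "migration")
})

test_that("years convert to generations linearly", {
  cfg <- global_config()
  expect_identical(years_to_generations(0, cfg), 0)
  expect_equal(years_to_generations(5.79, cfg), 1)
  expect_equal(years_to_generations(504000, cfg), 87046.6, tolerance = 1e-5)
  expect_error(years_to_generations(-1, cfg), "non-negative")
  set.seed(1)
  a <- runif(20, 0, 1e6); b <- runif(20, 0, 1e6)
  expect_equal(years_to_generations(a + b, cfg),
               years_to_generations(a, cfg) + years_to_generations(b, cfg))
})

test_that("models round-trip through JSON field-by-field", {
  for (build in list(build_gws_model, build_lsi_model)) {
    m <- build()
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    m2 <- read_model_json(path)
    expect_equal(m$populations, m2$populations)
    expect_equal(m$splits, m2$splits)
    expect_equal(m$migration, m2$migration)
    expect_equal(m$config$mutation_rate, m2$config$mutation_rate)
    expect_equal(m$config$generation_time, m2$config$generation_time)
  }
})

test_that("shipped presets load and match the in-code parameter sets", {
  for (nm in c("gws_fastsimcoal", "gws_jaatha", "lsi_fastsimcoal",
               "lsi_jaatha")) {
    m <- model_preset(nm)
    b <- if (startsWith(nm, "gws")) build_gws_model else build_lsi_model
    ref <- b(preset_params(nm))
    expect_equal(m$populations, ref$populations, info = nm)
    expect_equal(m$splits, ref$splits, info = nm)
    expect_equal(m$migration, ref$migration, info = nm)
  }
  # Jaatha preset carries its own divergence times
  mj <- model_preset("gws_jaatha")
  expect_equal(sort(unique(mj$splits$time)), c(31.2e3, 107e3, 428e3))
})

test_that("an outgroup attaches at the root with its own size and depth", {
  m <- attach_outgroup(build_gws_model())
  expect_true("OUT" %in% m$populations$name)
  og <- m$splits[m$splits$derived_pop == "OUT", ]
  expect_equal(og$ancestral_pop, "ANC")
  expect_equal(og$time, 1e7)
  expect_equal(m$populations$ne_present[m$populations$name == "OUT"], 1e4)
})
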