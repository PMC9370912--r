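# Preset registry: lookup, catalog, validation, sparse-override structure.

test_that("the catalog covers all shipped rhythms and round-trips", {
  cat <- list_presets()
  expect_gte(nrow(cat), 17)
  expect_false(anyDuplicated(paste(cat$model, cat$rhythm)) > 0)
  for (i in seq_len(nrow(cat))) {
    pr <- get_preset(cat$model[i], cat$rhythm[i])
    expect_s3_class(pr, "rhythm_preset")
    expect_identical(pr$model, cat$model[i])
    expect_identical(pr$rhythm, cat$rhythm[i])
  }
  # deterministic ordering
  expect_identical(cat, list_presets())
})

test_that("presets reproduce the tabulated parameter rows", {
  st <- get_preset("reaction_diffusion", "sinus_tachycardia")
  expect_equal(st$params$H, 2.848)
  expect_equal(st$params$K, c(0, -0.1, 0, 0))
  expect_equal(st$params$Gamma_t, 21)
  expect_equal(st$params$C, 1.35) # inherited from the normal row
  expect_equal(st$params$beta, 4)

  vf <- get_preset("ring", "ventricular_fibrillation")
  expect_equal(vf$params$nodes$SA$e, 6)
  expect_equal(vapply(vf$params$nodes, `[[`, numeric(1), "omega"),
               c(SA = 7.33, AV = 7.33, HP = 7.33))
  expect_equal(vapply(vf$params$nodes, `[[`, numeric(1), "rho"),
               c(SA = 1, AV = 1, HP = 20))
  expect_equal(vf$params$beta_T, 16)
  expect_equal(vf$params$beta_G, 0.0012)

  qn <- get_preset("quasi_periodic", "normal")
  expect_equal(unlist(qn$params$kernels$R[c("a", "b", "theta")]),
               c(a = 30, b = 0.1, theta = 0))
  expect_equal(unlist(qn$params$kernels$Q[c("a", "b", "theta")]),
               c(a = -0.5, b = 0.1, theta = -pi / 12))

  hn <- get_preset("heterogeneous", "normal")
  expect_equal(hn$params$pacemakers$SA$a, 40)
  expect_equal(hn$params$pacemakers$AV$tau, 0.092)
  expect_equal(hn$params$muscles$QRS$C, 9e-5)
  expect_equal(hn$params$z0, 0.2)
})

test_that("unknown presets fail with the list of valid rhythms", {
  expect_error(get_preset("ring", "nope"), "sinus_bradycardia")
  expect_error(get_preset("typo", "normal"), "must be one of")
})

test_that("returned presets are independent copies", {
  a <- get_preset("reaction_diffusion", "normal")
  a$params$H <- 999
  b <- get_preset("reaction_diffusion", "normal")
  expect_equal(b$params$H, 3)
})

test_that("arrhythmia presets differ from normal only in their stated fields", {
  expected <- list(
    reaction_diffusion = list(
      sinus_tachycardia = c("H", "K1", "K2", "K3", "K4", "time_scale"),
      atrial_flutter = c("H", "K1", "K2", "K3", "K4", "time_scale"),
      ventricular_tachycardia = c("H", "K1", "K2", "K3", "K4", "time_scale"),
      ventricular_flutter = c("H", "K1", "K2", "K3", "K4", "time_scale")
    ),
    ring = list(
      ventricular_flutter = c("k.AV_SA", "time_scale"),
      sinus_bradycardia = c("beta_G", "k.HP_AV", "time_scale"),
      ventricular_fibrillation = c("nodes.SA.e", "nodes.SA.omega",
                                   "nodes.AV.omega", "nodes.HP.omega")
    ),
    heterogeneous = list(
      complete_SA_AV_block = "pacemakers.AV.K",
      complete_AV_HP_block = "pacemakers.HP.K"
    )
  )
  for (model in names(expected)) {
    for (rhythm in names(expected[[model]])) {
      expect_setequal(preset_diff(model, rhythm), expected[[model]][[rhythm]])
    }
  }
})

test_that("validate_preset reports every violation of a broken preset", {
  ok <- validate_preset(file.path(preset_dir(),
                                  "reaction_diffusion_atrial_flutter.json"))
  expect_s3_class(ok, "rhythm_preset")

  raw <- ecgsim:::read_preset_file(
    file.path(preset_dir(), "quasi_periodic_normal.json")
  )
  raw$params$kernels$R$b <- 0
  rep1 <- validate_preset(raw)
  expect_s3_class(rep1, "preset_validation_report")
  expect_false(rep1$valid)
  expect_true(any(grepl("width must be positive", rep1$problems)))

  raw2 <- ecgsim:::read_preset_file(
    file.path(preset_dir(), "reaction_diffusion_normal.json")
  )
  raw2$params$K <- raw2$params$K[1:3]
  raw2$gain <- 9
  rep2 <- validate_preset(raw2)
  expect_false(rep2$valid)
  expect_true(any(grepl("K must be numeric of length 4", rep2$problems)))
  expect_true(any(grepl("gain", rep2$problems)))

  raw3 <- list(model = "reaction_diffusion", rhythm = "x")
  rep3 <- validate_preset(raw3)
  expect_true(any(grepl("missing field: params", rep3$problems)))
})

test_that("gain is confined to the device output range", {
  expect_error(get_preset("ring", "normal", gain = 0.1), "0.5-4")
  expect_error(get_preset("ring", "normal", gain = 5), "0.5-4")
  pr <- get_preset("ring", "normal", gain = 2)
  expect_equal(pr$gain, 2)
})

test_that("dotted-path overrides mirror the parameter-settings menu", {
  pr <- get_preset("heterogeneous", "normal",
                   overrides = list("pacemakers.AV.K" = 0))
  expect_equal(pr$params$pacemakers$AV$K, 0)
  expect_error(
    get_preset("heterogeneous", "normal", overrides = list("nope.x" = 1)),
    "unknown parameter override"
  )
})

test_that("preset tidiers expose parameters and summaries", {
  pr <- get_preset("quasi_periodic", "sinus_bradycardia")
  td <- tidy(pr)
  expect_true(all(c("parameter", "value") %in% names(td)))
  expect_equal(td$value[td$parameter == "kernels.Pminus.theta"], -3 * pi / 8)
  gl <- glance(pr)
  expect_identical(gl$rhythm, "sinus_bradycardia")
  expect_equal(nrow(gl), 1)
})
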