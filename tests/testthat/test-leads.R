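# Einthoven / Goldberger algebra and 12-lead assembly.

test_that("limb and augmented leads match direct substitution", {
  e <- tibble::tibble(RA = 1, LA = 0.5, LL = 0.2)
  l <- limb_leads(e)
  expect_equal(unlist(l), c(I = -0.5, II = -0.8, III = -0.3))
  expect_equal(l$II, l$I + l$III)
  a <- augmented_leads(e)
  expect_equal(unlist(a), c(aVR = 0.65, aVL = -0.1, aVF = -0.55))
  expect_equal(a$aVR + a$aVL + a$aVF, 0)

  # common-mode rejection
  e0 <- tibble::tibble(RA = 0.3, LA = 0.3, LL = 0.3)
  expect_true(all(unlist(limb_leads(e0)) == 0))
  expect_true(all(unlist(augmented_leads(e0)) == 0))

  expect_error(limb_leads(list(RA = 1:3, LA = 1:2, LL = 1:3)), "equal")
})

test_that("lead identities hold to a few ulps and are offset invariant", {
  e <- random_electrodes(1000, seed = 7)
  l <- limb_leads(e)
  a <- augmented_leads(e)
  expect_true(all(abs(l$II - (l$I + l$III)) <= ulp_bound(l$I, l$II, l$III)))
  expect_true(all(abs(a$aVR + a$aVL + a$aVF) <= ulp_bound(a$aVR, a$aVL, a$aVF)))

  shift <- e
  shift$RA <- shift$RA + 0.77; shift$LA <- shift$LA + 0.77
  shift$LL <- shift$LL + 0.77
  expect_equal(limb_leads(shift), l)
  expect_equal(augmented_leads(shift), a)
})

test_that("electrode recovery inverts the lead map in the zero-sum gauge", {
  el <- solve_electrode_potentials(1, 2)
  expect_equal(unlist(el), c(RA = -1, LA = 0, LL = 1))
  expect_equal(limb_leads(el)$III, 1) # III = II - I

  expect_equal(unlist(solve_electrode_potentials(0, 0)), c(RA = 0, LA = 0, LL = 0))

  set.seed(3)
  I <- stats::rnorm(200); II <- stats::rnorm(200)
  el2 <- solve_electrode_potentials(I, II)
  expect_equal(el2$RA + el2$LA + el2$LL, rep(0, 200), tolerance = 1e-15)
  l2 <- limb_leads(el2)
  expect_equal(l2$I, I)
  expect_equal(l2$II, II)

  # restricted to zero-sum potentials the round trip is the identity
  e <- random_electrodes(100, seed = 11)
  cm <- (e$RA + e$LA + e$LL) / 3
  e0 <- tibble::tibble(RA = e$RA - cm, LA = e$LA - cm, LL = e$LL - cm)
  l0 <- limb_leads(e0)
  back <- solve_electrode_potentials(l0$I, l0$II)
  expect_equal(as.data.frame(back), as.data.frame(e0), tolerance = 1e-12)
})

test_that("the 12-lead profile satisfies the lead-set invariants", {
  pr <- get_preset("heterogeneous", "normal")
  tr <- integrate_model("heterogeneous", pr$params, duration = 20)
  ls <- twelve_lead_profile(tr, fs = 250, gain = 1, transient = 4)
  expect_setequal(ecg_channels(ls), c("I", "II", "III", "aVR", "aVL", "aVF",
                                      paste0("V", 1:6)))
  expect_equal(ls$II, ls$I + ls$III, tolerance = 1e-12)
  expect_equal(ls$aVR + ls$aVL + ls$aVF, rep(0, nrow(ls)), tolerance = 1e-12)
  expect_equal(max(abs(ls$II - median(ls$II))), 1, tolerance = 1e-9)

  # equal V-lead weight rows give identical precordial traces
  p2 <- pr$params
  vrows <- p2$lead_weights$channel %in% paste0("V", 1:6)
  p2$lead_weights[vrows, c("a1", "a2", "a3", "a4", "z0")] <-
    list(0.1, 0.05, 1, 0.3, 0.2)
  ls2 <- twelve_lead_profile(tr, p2, fs = 250, gain = 1, transient = 4)
  for (v in paste0("V", 2:6)) expect_identical(ls2[[v]], ls2$V1)

  # a missing weight row is reported by channel name
  p3 <- pr$params
  p3$lead_weights <- p3$lead_weights[p3$lead_weights$channel != "V4", ]
  expect_error(twelve_lead_profile(tr, p3), "V4")
})
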