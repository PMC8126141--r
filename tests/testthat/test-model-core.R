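test_that("k4 follows from the acid dissociation constant", {
  # frozen from direct arithmetic: 10^(-pKa) * k_minus4
  expect_equal(k4_from_pka(6.8, 1e10), 1584.893192, tolerance = 1e-9)
  expect_equal(k4_from_pka(6.5, 1e10), 3162.277660, tolerance = 1e-9)
  expect_identical(k4_from_pka(0, 1), 1)
  expect_error(k4_from_pka(6.8, 0), "k_minus4")
  expect_error(k4_from_pka(6.8, -1), "k_minus4")
  expect_error(k4_from_pka(-1, 1e10), "pka")
  expect_error(k4_from_pka(15, 1e10), "pka")
})

test_that("default constants carry the literature values", {
  k <- default_constants
  expect_identical(k$k1, 1.7e7)
  expect_identical(k$k2, 2.6e7)
  expect_identical(k$k3, 1.1e3)
  expect_identical(k$k5, 1.7e6)
  expect_identical(k$k6, 5.8e4)
  expect_identical(k$kP, 1e-7)
  expect_identical(k$kD4, 320)
  expect_identical(k$kD5, 320)
  expect_identical(k$kD7, 320)
  # derived k4 stays consistent with its defining identity
  expect_equal(k$k4, 10^(-k$pka) * k$k_minus4, tolerance = 1e-12)
  expect_error(model_constants(k1 = -1), "k1")
  expect_error(model_constants(kP = 0), "kP")
})

test_that("treatment regimes reproduce the four dose combinations", {
  doses <- list(
    nonselective_synergistic = c(1e-3, 1e-3),
    nonselective_nonsynergistic = c(1e-3, 0),
    selective_synergistic = c(1e-6, 1e-3),
    selective_nonsynergistic = c(1e-6, 0))
  for (rg in names(doses)) {
    sc <- treatment_scenario(rg)
    expect_identical(c(sc$h2o2_ec0, sc$no2_ec0), doses[[rg]], info = rg)
  }
  expect_setequal(canonical_regimes(), names(doses))
  expect_error(treatment_scenario("mystery_regime"), "unknown regime")
  expect_error(treatment_scenario(h2o2_ec0 = -1, no2_ec0 = 0),
               "non-negative")
  expect_error(treatment_scenario(), "regime label")
})

test_that("steady-state H2O2 matches the closed form and its limits", {
  k <- default_constants
  # independent arithmetic oracle, written out in full
  oracle <- function(cat0, c5 = 1e-4, c6 = 1e-7)
    1e-7 / (1.7e7 * cat0 + 1.1e3 * c5 * c6)
  for (cat0 in c(1e-8, 1e-7, 3e-6, 1e-5)) {
    expect_equal(steady_state_h2o2(k, cat0), oracle(cat0),
                 tolerance = 1e-12)
  }
  # frozen decade checks: ~1e-7 M at low catalase, ~1e-10 M at high
  expect_equal(steady_state_h2o2(k, 1e-8), 5.882353e-7, tolerance = 1e-6)
  expect_equal(steady_state_h2o2(k, 1e-5), 5.882349e-10, tolerance = 1e-6)
  expect_identical(floor(log10(steady_state_h2o2(k, 1e-8))), -7)
  expect_identical(floor(log10(steady_state_h2o2(k, 1e-5))), -10)
  # nitrite-free limiting form is exactly kP / (k1 cat0)
  expect_identical(steady_state_h2o2(k, 1e-6, c5_ic = 0),
                   k$kP / (k$k1 * 1e-6))
  expect_error(steady_state_h2o2(k, 0), "cat0")
  expect_error(steady_state_h2o2(k, -1e-8), "cat0")
})

test_that("steady-state H2O2 is monotone in catalase and production", {
  cats <- 10^seq(-8, -5, length.out = 25)
  vals <- steady_state_h2o2(default_constants, cats)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0))
  kps <- seq(1e-8, 1e-6, length.out = 20)
  v2 <- vapply(kps, function(kp)
    steady_state_h2o2(model_constants(kP = kp), 1e-6), numeric(1))
  expect_true(all(diff(v2) > 0))
})

test_that("the initial state encodes the pre-treatment system", {
  ph <- cell_phenotype(920, 1e-8)
  y <- initial_state(ph, selective)
  expect_named(y, state_names())
  expect_identical(y[["c1_ec"]], 1e-6)
  expect_identical(y[["c5_ec"]], 0)
  expect_identical(y[["c6_ec"]], 1e-7)
  expect_identical(y[["c8_ec"]], 1e-3)
  expect_identical(y[["c2"]], 1e-8)
  expect_identical(y[["c5_ic"]], 1e-4)
  # ONOO-, ONOOH, compound I and the sinks all start at zero
  for (v in c("c3", "c4_ec", "c4_ic", "c7_ec", "c7_ic",
              "sink_ec", "sink_ic"))
    expect_identical(y[[v]], 0, info = v)
  expect_equal(y[["c1_ic"]], steady_state_h2o2(default_constants, 1e-8),
               tolerance = 1e-15)
  y2 <- initial_state(ph, treatment_scenario("nonselective_synergistic"))
  expect_identical(y2[["c1_ec"]], 1e-3)
  expect_identical(y2[["c5_ec"]], 1e-3)
})

test_that("the derivative implements the rate equations", {
  k <- default_constants
  ph <- cell_phenotype(920, 1e-8)
  y <- initial_state(ph, selective)
  d <- derivative(y, ph)
  # EC H2O2 at t=0 (no nitrite): pure diffusive loss, frozen arithmetic
  c1ss <- 1e-7 / (1.7e7 * 1e-8 + 1.1e3 * 1e-4 * 1e-7)
  expect_equal(d[["c1_ec"]], -920 * (1e-6 - c1ss), tolerance = 1e-12)
  expect_equal(d[["c1_ec"]], -3.788235e-4, tolerance = 1e-6)
  # catalase cycle is internally conservative, term by term
  expect_identical(d[["c2"]] + d[["c3"]], 0)
  # CO2 only reacts through the ONOO- channel
  expect_identical(d[["c8_ec"]], 0)
  # with everything at zero only mitochondrial production remains
  y0 <- setNames(numeric(16), state_names())
  d0 <- derivative(y0, ph)
  expect_identical(d0[["c1_ic"]], k$kP)
  expect_identical(sum(abs(d0[setdiff(state_names(), "c1_ic")])), 0)
  expect_error(derivative(c(y[-1], c1_ec = NaN), ph), "finite")
})

test_that("diffusion terms are antisymmetric between compartments", {
  k <- default_constants
  # suppress diffusion (constants must stay positive, so use a negligible
  # rate) and difference against the full derivative to isolate the flux
  tiny <- model_constants(kD4 = 1e-300, kD5 = 1e-300, kD7 = 1e-300)
  for (y in random_states(6)) {
    ph <- cell_phenotype(runif(1, 100, 2000), 1e-6)
    d_full <- derivative(y, ph, k)
    d_noD <- derivative(y, ph, tiny)
    phi0 <- cell_phenotype(1e-300, 1e-6)
    d_nok1 <- derivative(y, phi0, k)
    # H2O2 flux via kd1
    flux1_ec <- d_nok1[["c1_ec"]] - derivative(y, phi0, tiny)[["c1_ec"]]
    for (sp in c("c4", "c5", "c7")) {
      fe <- d_full[[paste0(sp, "_ec")]] - d_noD[[paste0(sp, "_ec")]]
      fi <- d_full[[paste0(sp, "_ic")]] - d_noD[[paste0(sp, "_ic")]]
      expect_equal(fe, -fi, tolerance = 1e-9, info = sp)
    }
    fe1 <- d_full[["c1_ec"]] - d_nok1[["c1_ec"]]
    fi1 <- d_full[["c1_ic"]] - d_nok1[["c1_ic"]]
    expect_equal(fe1, -fi1, tolerance = 1e-9)
  }
})

test_that("nitrogen is conserved by construction of the rate equations", {
  nset <- c("c4_ec", "c5_ec", "c7_ec", "c4_ic", "c5_ic", "c7_ic",
            "sink_ec", "sink_ic")
  for (y in random_states(8, seed = 7)) {
    d <- derivative(y, cell_phenotype(500, 1e-6))
    scale <- max(abs(d))
    expect_lt(abs(sum(d[nset])), 1e-12 * scale)
  }
})

test_that("the steady-state initialization is a fixed point of c1_ic", {
  k <- default_constants
  for (cat0 in c(1e-8, 1e-6, 1e-5)) {
    c1ss <- steady_state_h2o2(k, cat0)
    # match the extracellular concentration so the diffusion term vanishes
    sc <- treatment_scenario(h2o2_ec0 = c1ss, no2_ec0 = 0)
    ph <- cell_phenotype(920, cat0)
    d <- derivative(initial_state(ph, sc), ph)
    expect_lt(abs(d[["c1_ic"]]), 1e-12 * k$kP)
  }
})
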