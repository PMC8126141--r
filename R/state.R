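#' @keywords internal
"_PACKAGE"

# State vector layout, shared by every routine that touches a SystemState.
# EC then IC then the cumulative ONOOCOO- sinks. c2/c3 are the two enzyme
# states of catalase (IC only); H+ (c6) and CO2 (c8) are dynamic.
.state_names <- c("c1_ec", "c4_ec", "c5_ec", "c6_ec", "c7_ec", "c8_ec",
                  "c1_ic", "c2", "c3", "c4_ic", "c5_ic", "c6_ic",
                  "c7_ic", "c8_ic", "sink_ec", "sink_ic")

#' Names of the state-vector components
#'
#' Species concentrations in both compartments (suffixes `_ec`/`_ic`; `c2`
#' and `c3` are the intracellular catalase states CATFeIII and compound I),
#' plus the cumulative ONOOCOO- sinks per compartment used for
#' nitrogen-balance bookkeeping.
#'
#' @return Character vector of length 16.
#' @export
state_names <- function() .state_names

#' Steady-state intracellular H2O2 concentration
#'
#' Before treatment, intracellular H2O2 is at the balance between constant
#' mitochondrial production (kP) and first-order consumption by catalase and
#' by the nitrite pathway, with all catalase as CATFeIII:
#' \deqn{c_{1,ss} = \frac{k_P}{k_1 \, CAT_0 + k_3 \, c_5 \, c_6}}
#' This value is used as the initial intracellular H2O2 concentration, so
#' that the pre-treatment system starts at (approximate) rest.
#'
#' @param constants A [model_constants()] object.
#' @param cat0 Initial catalase concentration, M (> 0).
#' @param c5_ic Intracellular NO2- concentration, M (default 1e-4).
#' @param c6_ic Intracellular H+ concentration, M (default 1e-7, pH 7).
#' @return Steady-state H2O2 concentration, M.
#' @examples
#' steady_state_h2o2(model_constants(), cat0 = 1e-8)
#' @export
steady_state_h2o2 <- function(constants = model_constants(), cat0,
                              c5_ic = 1e-4, c6_ic = 1e-7) {
  stopifnot(inherits(constants, "ptl_constants"),
            is.numeric(cat0), is.numeric(c5_ic), is.numeric(c6_ic))
  if (any(cat0 <= 0)) stop("cat0 must be strictly positive")
  constants$kP / (constants$k1 * cat0 + constants$k3 * c5_ic * c6_ic)
}

#' Initial state of the two-compartment system
#'
#' At t = 0 the extracellular compartment holds the treatment dose of H2O2
#' and NO2- plus physiological H+ (1e-7 M) and CO2 (1e-3 M); ONOO- and
#' ONOOH start at zero in both compartments. Intracellularly, H2O2 starts
#' at its pre-treatment steady state ([steady_state_h2o2()]), all catalase
#' is in the CATFeIII form (compound I = 0), NO2- is 1e-4 M, and H+/CO2
#' match the extracellular values. Both ONOOCOO- sinks start at zero.
#'
#' @param phenotype A [cell_phenotype()].
#' @param scenario A [treatment_scenario()].
#' @param constants A [model_constants()].
#' @return Named numeric vector over [state_names()], concentrations in M.
#' @export
initial_state <- function(phenotype, scenario,
                          constants = model_constants()) {
  stopifnot(inherits(phenotype, "ptl_phenotype"),
            inherits(scenario, "ptl_scenario"))
  c5_ic0 <- 1e-4
  c6_0 <- 1e-7
  c8_0 <- 1e-3
  y <- c(c1_ec = scenario$h2o2_ec0, c4_ec = 0, c5_ec = scenario$no2_ec0,
         c6_ec = c6_0, c7_ec = 0, c8_ec = c8_0,
         c1_ic = steady_state_h2o2(constants, phenotype$cat0, c5_ic0, c6_0),
         c2 = phenotype$cat0, c3 = 0, c4_ic = 0, c5_ic = c5_ic0,
         c6_ic = c6_0, c7_ic = 0, c8_ic = c8_0,
         sink_ec = 0, sink_ic = 0)
  y[.state_names]
}

# Flatten constants + phenotype to the parameter vector used by the fast
# right-hand side. Order matters; .rhs_raw indexes positionally.
.pack_params <- function(phenotype, constants) {
  c(constants$k1, constants$k2, constants$k3, constants$k4,
    constants$k_minus4, constants$k5, constants$k6, constants$kP,
    phenotype$kd1, constants$kD4, constants$kD5, constants$kD7)
}

# Right-hand side of the 14-species system (+2 sink integrals), positional
# for speed: called ~1e4-1e6 times per integration. y follows .state_names,
# p follows .pack_params.
.rhs_raw <- function(y, p) {
  c1e <- y[1L]; c4e <- y[2L]; c5e <- y[3L]; c6e <- y[4L]
  c7e <- y[5L]; c8e <- y[6L]
  c1i <- y[7L]; c2 <- y[8L]; c3 <- y[9L]; c4i <- y[10L]
  c5i <- y[11L]; c6i <- y[12L]; c7i <- y[13L]; c8i <- y[14L]

  r3e <- p[3L] * c1e * c5e * c6e        # NO2- + H2O2 + H+ -> ONOOH (EC)
  r4e <- p[4L] * c7e                    # ONOOH -> ONOO- + H+
  rm4e <- p[5L] * c4e * c6e             # ONOO- + H+ -> ONOOH
  r6e <- p[7L] * c4e * c8e              # ONOO- + CO2 -> ONOOCOO-

  r1 <- p[1L] * c1i * c2                # CATFeIII + H2O2 -> compound I
  r2 <- p[2L] * c1i * c3                # compound I + H2O2 -> CATFeIII + O2
  r3i <- p[3L] * c1i * c5i * c6i
  r4i <- p[4L] * c7i
  rm4i <- p[5L] * c4i * c6i
  r5 <- p[6L] * c2 * c4i                # catalase-mediated ONOO- decomposition
  r6i <- p[7L] * c4i * c8i

  d1 <- p[9L] * (c1e - c1i)             # Fick fluxes, EC -> IC positive
  d4 <- p[10L] * (c4e - c4i)
  d5 <- p[11L] * (c5e - c5i)
  d7 <- p[12L] * (c7e - c7i)

  c(-r3e - d1,                          # c1_ec
    r4e - rm4e - r6e - d4,              # c4_ec
    -r3e - d5,                          # c5_ec
    -r3e + r4e - rm4e,                  # c6_ec
    r3e - r4e + rm4e - d7,              # c7_ec
    -r6e,                               # c8_ec
    -r1 - r2 - r3i + d1 + p[8L],        # c1_ic (+ mitochondrial kP)
    -r1 + r2,                           # c2
    r1 - r2,                            # c3
    r4i - rm4i - r5 - r6i + d4,         # c4_ic
    -r3i + r5 + d5,                     # c5_ic
    -r3i + r4i - rm4i,                  # c6_ic
    r3i - r4i + rm4i + d7,              # c7_ic
    -r6i,                               # c8_ic
    r6e,                                # sink_ec
    r6i)                                # sink_ic
}

#' Time derivative of the system state
#'
#' Evaluates the full set of mass-action rate equations of both
#' compartments, the membrane diffusion terms (equal magnitude, opposite
#' sign in EC and IC for H2O2, ONOO-, NO2- and ONOOH), the constant
#' mitochondrial H2O2 production, and the cumulative ONOOCOO- sink rates
#' (k6 channel) per compartment.
#'
#' @param state Named numeric vector over [state_names()], M.
#' @param phenotype A [cell_phenotype()].
#' @param constants A [model_constants()].
#' @return Named numeric vector of time derivatives, M s-1.
#' @export
derivative <- function(state, phenotype, constants = model_constants()) {
  stopifnot(inherits(phenotype, "ptl_phenotype"))
  if (!all(is.finite(state)))
    stop("state contains non-finite values")
  y <- state[.state_names]
  if (anyNA(y))
    stop("state must be named over state_names()")
  dy <- .rhs_raw(as.numeric(y), .pack_params(phenotype, constants))
  names(dy) <- .state_names
  dy
}
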