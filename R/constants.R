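#' Acid-dissociation-derived rate constant for ONOOH deprotonation
#'
#' The forward rate of ONOOH -> ONOO- + H+ is tied to the reverse
#' (diffusion-limited) recombination rate through the acid dissociation
#' constant: k4 = Ka * k_minus4 = 10^(-pKa) * k_minus4.
#'
#' @param pka Acid dissociation pKa of peroxynitrous acid (dimensionless,
#'   literature range 6.5-6.8 at 25 C).
#' @param k_minus4 Recombination rate constant ONOO- + H+ -> ONOOH
#'   (M-1 s-1, ~1e10).
#' @return Forward rate constant k4 in s-1.
#' @examples
#' k4_from_pka(6.8, 1e10)
#' @export
k4_from_pka <- function(pka, k_minus4) {
  stopifnot(is.numeric(pka), length(pka) == 1L, is.finite(pka),
            is.numeric(k_minus4), length(k_minus4) == 1L, is.finite(k_minus4))
  if (pka < 0 || pka > 14)
    stop("pka must lie in [0, 14], got ", pka)
  if (k_minus4 <= 0)
    stop("k_minus4 must be strictly positive, got ", k_minus4)
  10^(-pka) * k_minus4
}

#' Rate, diffusion and production constants of the redox network
#'
#' Bundles every fixed kinetic parameter of the two-compartment model:
#' the two-step catalase cycle (k1, k2), peroxynitrous acid formation from
#' nitrite and H2O2 (k3, third order), the ONOOH/ONOO- acid-base pair
#' (k4 derived from pKa, k_minus4), catalase-mediated ONOO- decomposition
#' (k5), the CO2-catalyzed ONOO- sink (k6), mitochondrial H2O2 production
#' (kP), and the membrane diffusion rate constants of ONOO-, NO2- and
#' ONOOH (kD4, kD5, kD7). The H2O2 diffusion constant kD1 is a cell
#' phenotype, not a model constant; see [cell_phenotype()].
#'
#' Defaults are the literature values used throughout: k1 = 1.7e7 and
#' k2 = 2.6e7 M-1 s-1 (mammalian catalases), k3 = 1.1e3 M-2 s-1,
#' pKa = 6.8 with k_minus4 = 1e10 M-1 s-1, k5 = 1.7e6 M-1 s-1,
#' k6 = 5.8e4 M-1 s-1, kP = 1e-7 M s-1, kD4 = kD5 = kD7 = 320 s-1.
#'
#' @param k1,k2 Catalase cycle rate constants, M-1 s-1
#'   (CATFeIII + H2O2 -> compound I; compound I + H2O2 -> CATFeIII + O2).
#' @param k3 NO2- + H2O2 + H+ -> ONOOH rate constant, M-2 s-1.
#' @param pka ONOOH acid dissociation pKa (k4 is derived from it).
#' @param k_minus4 ONOO- + H+ -> ONOOH rate constant, M-1 s-1.
#' @param k5 Catalase-mediated ONOO- decomposition rate constant, M-1 s-1.
#' @param k6 ONOO- + CO2 rate constant, M-1 s-1.
#' @param kP Mitochondrial H2O2 production rate, M s-1.
#' @param kD4,kD5,kD7 Membrane diffusion rate constants of ONOO-, NO2-,
#'   ONOOH, s-1.
#' @return An object of class `ptl_constants`: a named list with the above
#'   fields plus the derived `k4` (s-1).
#' @export
model_constants <- function(k1 = 1.7e7, k2 = 2.6e7, k3 = 1.1e3,
                            pka = 6.8, k_minus4 = 1e10,
                            k5 = 1.7e6, k6 = 5.8e4, kP = 1e-7,
                            kD4 = 320, kD5 = 320, kD7 = 320) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, pka = pka, k_minus4 = k_minus4,
            k5 = k5, k6 = k6, kP = kP, kD4 = kD4, kD5 = kD5, kD7 = kD7)
  if (!all(is.finite(vals)))
    stop("all model constants must be finite numbers")
  bad <- names(vals)[vals <= 0]
  if (length(bad))
    stop("model constants must be strictly positive: ",
         paste(bad, collapse = ", "))
  obj <- as.list(vals)
  obj$k4 <- k4_from_pka(pka, k_minus4)
  structure(obj, class = "ptl_constants")
}

#' @export
print.ptl_constants <- function(x, ...) {
  cat("Redox network constants:\n")
  for (nm in names(x))
    cat(sprintf("  %-9s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Cell phenotype: the two independent variables of the model
#'
#' A cell is characterized by its H2O2 membrane diffusion rate constant
#' (a stand-in for aquaporin expression) and its initial intracellular
#' catalase concentration. Cancer-like cells have high `kd1` and low
#' `cat0`; normal-like cells the converse.
#'
#' @param kd1 H2O2 membrane diffusion rate constant, s-1 (swept over
#'   100-2000; reference value 920).
#' @param cat0 Initial intracellular catalase (CATFeIII) concentration, M
#'   (swept over 1e-8 to 1e-5).
#' @return An object of class `ptl_phenotype`.
#' @export
cell_phenotype <- function(kd1 = 920, cat0 = 1e-6) {
  stopifnot(is.numeric(kd1), length(kd1) == 1L, is.finite(kd1),
            is.numeric(cat0), length(cat0) == 1L, is.finite(cat0))
  if (kd1 <= 0) stop("kd1 must be strictly positive, got ", kd1)
  if (cat0 <= 0) stop("cat0 must be strictly positive, got ", cat0)
  structure(list(kd1 = kd1, cat0 = cat0), class = "ptl_phenotype")
}

.regime_table <- data.frame(
  regime   = c("nonselective_synergistic", "nonselective_nonsynergistic",
               "selective_synergistic", "selective_nonsynergistic"),
  h2o2_ec0 = c(1e-3, 1e-3, 1e-6, 1e-6),
  no2_ec0  = c(1e-3, 0, 1e-3, 0),
  stringsAsFactors = FALSE
)

#' Treatment scenario: the extracellular dose of H2O2 and nitrite
#'
#' The treatment is modeled as an instantaneous addition of H2O2 and NO2-
#' to the extracellular compartment at t = 0. Four canonical regimes are
#' provided, crossing the selective (1 uM H2O2) / non-selective (1 mM H2O2)
#' dose with presence (1 mM) / absence of nitrite:
#' `"selective_nonsynergistic"` (1e-6 M, 0), `"selective_synergistic"`
#' (1e-6 M, 1e-3 M), `"nonselective_nonsynergistic"` (1e-3 M, 0) and
#' `"nonselective_synergistic"` (1e-3 M, 1e-3 M).
#'
#' @param regime One of the four canonical regime labels, or NULL to give
#'   concentrations directly.
#' @param h2o2_ec0 Initial extracellular H2O2, M (overrides the regime's).
#' @param no2_ec0 Initial extracellular NO2-, M (overrides the regime's).
#' @return An object of class `ptl_scenario` with fields `h2o2_ec0`,
#'   `no2_ec0`, `regime`.
#' @examples
#' treatment_scenario("selective_nonsynergistic")
#' treatment_scenario(h2o2_ec0 = 5e-6, no2_ec0 = 0)
#' @export
treatment_scenario <- function(regime = NULL, h2o2_ec0 = NULL, no2_ec0 = NULL) {
  if (!is.null(regime)) {
    i <- match(regime, .regime_table$regime)
    if (is.na(i))
      stop("unknown regime label '", regime, "'; valid labels: ",
           paste(.regime_table$regime, collapse = ", "))
    if (is.null(h2o2_ec0)) h2o2_ec0 <- .regime_table$h2o2_ec0[i]
    if (is.null(no2_ec0)) no2_ec0 <- .regime_table$no2_ec0[i]
  } else {
    if (is.null(h2o2_ec0) || is.null(no2_ec0))
      stop("give either a regime label or both h2o2_ec0 and no2_ec0")
    regime <- "custom"
  }
  stopifnot(is.numeric(h2o2_ec0), is.numeric(no2_ec0))
  if (h2o2_ec0 < 0 || no2_ec0 < 0)
    stop("initial concentrations must be non-negative")
  structure(list(h2o2_ec0 = h2o2_ec0, no2_ec0 = no2_ec0, regime = regime),
            class = "ptl_scenario")
}

#' The four canonical treatment regimes
#'
#' @return Character vector of the four regime labels accepted by
#'   [treatment_scenario()].
#' @export
canonical_regimes <- function() .regime_table$regime
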