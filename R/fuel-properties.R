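#' Empirical correlation registry
#'
#' The fuel-property estimates are composition-based QSPR correlations. Two
#' cetane-number routes are registered:
#' \describe{
#'   \item{per-species}{Krisnangkura-type: `CN = 46.3 + 5458/SV - 0.225 IV`,
#'     with SV and IV assembled per species from the weight percents.}
#'   \item{du-regression}{linear in the degree of unsaturation:
#'     `CN = 62.876 - 6.6684 DU`.}
#' }
#' Kinematic viscosity and density are linear in DU
#' (`KV = 5.2065 - 0.6316 DU`, `rho = 0.8726 + 0.0055 DU`), the higher
#' heating value follows Demirbas (`HHV = 49.43 - 0.041 SV - 0.015 IV`) and
#' the cold filter plugging point is linear in the long-chain saturation
#' factor (`CFPP = 3.1417 LCSF - 16.477`). Coefficients can be overridden to
#' swap in another published set.
#'
#' @param name `"per-species"` or `"du-regression"` (the CN route; all other
#'   properties share one set of coefficients).
#' @return A list of named coefficient vectors with a `name` field.
#' @export
fuel_correlations <- function(name = c("per-species", "du-regression")) {
  name <- match.arg(name)
  list(
    name = name,
    cn_per_species = c(intercept = 46.3, sv = 5458, iv = -0.225),
    cn_du = c(intercept = 62.876, du = -6.6684),
    kv_du = c(intercept = 5.2065, du = -0.6316),
    density_du = c(intercept = 0.8726, du = 0.0055),
    hhv = c(intercept = 49.43, sv = -0.041, iv = -0.015),
    cfpp = c(intercept = -16.477, lcsf = 3.1417)
  )
}

per_species_terms <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  if (length(profile$fractions) == 0 || sum(profile$fractions) <= 0) {
    stop("degenerate profile: no positive weight percents", call. = FALSE)
  }
  sp <- parse_species(names(profile$fractions))
  list(ni = unname(profile$fractions),
       d = sp$double_bonds,
       mw = methyl_ester_mw(sp$carbons, sp$double_bonds))
}

#' Saponification and iodine values from a FAME profile
#'
#' Mixture-level chemical indices assembled species by species from the
#' weight percents `Ni` and methyl-ester molecular weights `Mi`:
#' `SV = sum(560 Ni / Mi)` (mg KOH/g) and `IV = sum(254 D Ni / Mi)`
#' (g I2/100 g). Both are linear in the weight percents, so their values on
#' a raw (non-normalized) profile scale with the profile total.
#'
#' @param profile A [fame_profile()].
#' @return Numeric scalar.
#' @examples
#' oleate <- fame_profile(c("C18:1" = 100))
#' saponification_value(oleate)  # 188.9
#' iodine_value(oleate)          # 85.7
#' @export
saponification_value <- function(profile) {
  t <- per_species_terms(profile)
  sum(560 * t$ni / t$mw)
}

#' @rdname saponification_value
#' @export
iodine_value <- function(profile) {
  t <- per_species_terms(profile)
  sum(254 * t$d * t$ni / t$mw)
}

#' Cetane number from a FAME profile
#'
#' @inheritParams saponification_value
#' @param method Correlation route, see [fuel_correlations()].
#' @param correlations Coefficient registry (override to swap equation sets).
#' @return Estimated cetane number (dimensionless).
#' @export
cetane_number <- function(profile, method = c("per-species", "du-regression"),
                          correlations = fuel_correlations(method)) {
  method <- match.arg(method)
  if (method == "per-species") {
    sv <- saponification_value(profile)
    if (sv <= 0) stop("degenerate profile: saponification value is zero",
                      call. = FALSE)
    iv <- iodine_value(profile)
    co <- correlations$cn_per_species
    unname(co["intercept"] + co["sv"] / sv + co["iv"] * iv)
  } else {
    co <- correlations$cn_du
    unname(co["intercept"] + co["du"] * class_summary(profile)$du)
  }
}

#' Higher heating value from a FAME profile
#'
#' `HHV = 49.43 - 0.041 SV - 0.015 IV` (MJ/kg).
#'
#' @inheritParams cetane_number
#' @return MJ/kg.
#' @export
higher_heating_value <- function(profile,
                                 correlations = fuel_correlations()) {
  co <- correlations$hhv
  unname(co["intercept"] + co["sv"] * saponification_value(profile) +
           co["iv"] * iodine_value(profile))
}

check_du <- function(du) {
  if (is.na(du) || du < 0 || du > 3) {
    stop("degree of unsaturation must lie in [0, 3]", call. = FALSE)
  }
  du
}

#' DU- and LCSF-based property regressions
#'
#' Linear regressions on the [class_summary()] predictors: kinematic
#' viscosity at 40 C (mm^2/s) and density (g/cm^3) on the degree of
#' unsaturation, cold filter plugging point (degrees C) on the long-chain
#' saturation factor.
#'
#' @param summary A [class_summary()] (or a [fame_profile()], summarized on
#'   the fly).
#' @param correlations Coefficient registry.
#' @return Numeric scalar.
#' @examples
#' s <- class_summary(fame_profile(c("C18:1" = 100)))
#' kinematic_viscosity(s)
#' fuel_density(s)
#' cfpp(s)
#' @export
kinematic_viscosity <- function(summary, correlations = fuel_correlations()) {
  summary <- as_class_summary(summary)
  co <- correlations$kv_du
  unname(co["intercept"] + co["du"] * check_du(summary$du))
}

#' @rdname kinematic_viscosity
#' @export
fuel_density <- function(summary, correlations = fuel_correlations()) {
  summary <- as_class_summary(summary)
  co <- correlations$density_du
  unname(co["intercept"] + co["du"] * check_du(summary$du))
}

#' @rdname kinematic_viscosity
#' @export
cfpp <- function(summary, correlations = fuel_correlations()) {
  summary <- as_class_summary(summary)
  if (summary$lcsf < 0) stop("LCSF must be >= 0", call. = FALSE)
  co <- correlations$cfpp
  unname(co["intercept"] + co["lcsf"] * summary$lcsf)
}

as_class_summary <- function(x) {
  if (inherits(x, "class_summary")) return(x)
  if (inherits(x, "fame_profile")) return(class_summary(x))
  stop("expected a class_summary or fame_profile", call. = FALSE)
}

#' Full fuel-property report for a FAME profile
#'
#' Applies the whole correlation set to one profile and returns a classed
#' report: saponification value, iodine value, cetane number (by the chosen
#' route), higher heating value, density, kinematic viscosity, cold filter
#' plugging point, plus the DU/LCSF predictors and method tags. Property
#' math accepts the profile as printed (raw) or closed to 100%
#' (`normalize = TRUE`); the report records which was used.
#'
#' @param profile A [fame_profile()].
#' @param method Cetane-number route, see [fuel_correlations()].
#' @param normalize Normalize the profile to 100% before computing
#'   (default `FALSE`: use the composition as printed).
#' @param correlations Coefficient registry.
#' @return Object of class `fuel_property_report`.
#' @examples
#' p <- fame_profile(c("C16:0" = 28.85, "C18:1" = 52.58, "C18:2" = 12.45,
#'                     "C18:3" = 1.37, "C14:0" = 0.89, "C22:0" = 0.46,
#'                     "C15:0" = 0.1))
#' fuel_property_report(p, method = "du-regression")
#' @export
fuel_property_report <- function(profile,
                                 method = c("per-species", "du-regression"),
                                 normalize = FALSE,
                                 correlations = fuel_correlations(method)) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "fame_profile"))
  if (normalize) profile <- normalize_profile(profile)
  s <- class_summary(profile)
  sv <- saponification_value(profile)
  iv <- iodine_value(profile)
  structure(list(
    sample_id = profile$sample_id,
    sv = sv,
    iv = iv,
    cn = cetane_number(profile, method, correlations),
    hhv = higher_heating_value(profile, correlations),
    density = fuel_density(s, correlations),
    kv40 = kinematic_viscosity(s, correlations),
    cfpp = cfpp(s, correlations),
    du = s$du,
    lcsf = s$lcsf,
    method = method,
    normalized_input = profile$normalized
  ), class = "fuel_property_report")
}

#' @export
print.fuel_property_report <- function(x, ...) {
  cat(sprintf("Biodiesel property estimates for '%s' (%s CN route, %s input)\n",
              x$sample_id, x$method,
              if (x$normalized_input) "normalized" else "raw"))
  fmt <- function(v) formatC(v, digits = 4, format = "fg")
  cat(sprintf("  SV   %s mg KOH/g\n", fmt(x$sv)))
  cat(sprintf("  IV   %s g I2/100 g\n", fmt(x$iv)))
  cat(sprintf("  CN   %s\n", fmt(x$cn)))
  cat(sprintf("  HHV  %s MJ/kg\n", fmt(x$hhv)))
  cat(sprintf("  rho  %s g/cm^3\n", fmt(x$density)))
  cat(sprintf("  KV40 %s mm^2/s\n", fmt(x$kv40)))
  cat(sprintf("  CFPP %s degC\n", fmt(x$cfpp)))
  cat(sprintf("  DU %s  LCSF %s\n", fmt(x$du), fmt(x$lcsf)))
  invisible(x)
}

#' @export
as.data.frame.fuel_property_report <- function(x, ...) {
  data.frame(sample_id = x$sample_id, sv = x$sv, iv = x$iv, cn = x$cn,
             hhv = x$hhv, density = x$density, kv40 = x$kv40, cfpp = x$cfpp,
             du = x$du, lcsf = x$lcsf, method = x$method,
             normalized_input = x$normalized_input, stringsAsFactors = FALSE)
}

#' Biodiesel mass from lipid mass and transesterification efficiency
#'
#' `product = lipid_mass * efficiency`; the inverse
#' [transesterification_efficiency()] recovers the efficiency from the two
#' masses.
#'
#' @param lipid_mass Extracted lipid mass (g, or g/L), >= 0.
#' @param efficiency Fraction of lipid converted to FAME, in `[0, 1]`.
#' @return Product mass in the units of `lipid_mass`.
#' @examples
#' estimate_biodiesel_mass(6.8, 0.9177)
#' transesterification_efficiency(6.24, 6.8)  # fraction
#' @export
estimate_biodiesel_mass <- function(lipid_mass, efficiency) {
  if (any(lipid_mass < 0)) stop("lipid mass must be >= 0", call. = FALSE)
  if (any(efficiency < 0 | efficiency > 1)) {
    stop("efficiency must lie in [0, 1]", call. = FALSE)
  }
  lipid_mass * efficiency
}

#' @rdname estimate_biodiesel_mass
#' @param product_mass FAME mass recovered after transesterification.
#' @export
transesterification_efficiency <- function(product_mass, lipid_mass) {
  if (any(lipid_mass <= 0)) stop("lipid mass must be > 0", call. = FALSE)
  if (any(product_mass < 0)) stop("product mass must be >= 0", call. = FALSE)
  product_mass / lipid_mass
}
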