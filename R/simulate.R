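#' Parameters for the batch-growth simulator
#'
#' The generator emulates a batch single-cell-oil fermentation: logistic
#' biomass growth, Luedeking-Piret lipid formation (a growth-associated term
#' `alpha` and a non-growth-associated term `beta`), and sequential sugar
#' consumption in a stated preference order (glucose before xylose before
#' arabinose, the diauxie the organism shows on mixed hydrolysate sugars).
#' Defaults emulate a 120-h alkali-saccharified-hydrolysate batch ending
#' near 12.6 g/L DCW and 7.0 g/L lipid with ~46.5 g/L total initial sugars.
#'
#' @param X0 Initial biomass, g/L (> 0).
#' @param K Carrying capacity, g/L (> X0).
#' @param mu Specific growth rate, 1/h.
#' @param alpha Growth-associated lipid yield, g lipid / g biomass.
#' @param beta Non-growth-associated lipid rate, g lipid / g biomass / h.
#' @param sugar_init Named vector of initial sugar concentrations, g/L; the
#'   name order is the consumption preference order.
#' @param sugar_rates Consumption rate of each sugar while it is the active
#'   carbon source, g/L/h (same names/order as `sugar_init`).
#' @param noise_sd Additive Gaussian measurement noise, g/L.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `growth_sim_params`.
#' @export
growth_sim_params <- function(X0 = 0.1, K = 12.58, mu = 0.1,
                              alpha = 0.418, beta = 0.002,
                              sugar_init = c(glucose = 28.05, xylose = 18.13,
                                             arabinose = 0.29),
                              sugar_rates = c(glucose = 0.34, xylose = 0.60,
                                              arabinose = 0.05),
                              noise_sd = 0, seed = NULL) {
  if (X0 <= 0 || K <= X0) stop("need 0 < X0 < K", call. = FALSE)
  if (mu < 0 || alpha < 0 || beta < 0 || noise_sd < 0) {
    stop("rates and noise must be >= 0", call. = FALSE)
  }
  if (!identical(names(sugar_init), names(sugar_rates))) {
    stop("sugar_init and sugar_rates must share names and order",
         call. = FALSE)
  }
  if (any(sugar_init < 0) || any(sugar_rates < 0)) {
    stop("sugar parameters must be >= 0", call. = FALSE)
  }
  structure(list(X0 = X0, K = K, mu = mu, alpha = alpha, beta = beta,
                 sugar_init = sugar_init, sugar_rates = sugar_rates,
                 noise_sd = noise_sd, seed = seed),
            class = "growth_sim_params")
}

#' Closed-form logistic biomass
#'
#' `X(t) = K / (1 + ((K - X0)/X0) exp(-mu t))`, the noiseless biomass
#' trajectory used by [simulate_timecourse()].
#'
#' @param t Time(s), h.
#' @param X0,K,mu See [growth_sim_params()].
#' @return Biomass, g/L.
#' @export
logistic_biomass <- function(t, X0, K, mu) {
  K / (1 + ((K - X0) / X0) * exp(-mu * t))
}

cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

sequential_sugars <- function(times, init, rates) {
  # sugar i is consumed at its own rate, starting when all preceding sugars
  # in the preference order are exhausted
  durations <- ifelse(init > 0, ifelse(rates > 0, init / rates, Inf), 0)
  starts <- c(0, cumsum(durations))[seq_along(init)]
  out <- vapply(seq_along(init), function(i) {
    pmax(0, init[i] - rates[i] * pmax(0, times - starts[i]))
  }, numeric(length(times)))
  out <- matrix(out, nrow = length(times),
                dimnames = list(NULL, names(init)))
  as.data.frame(out)
}

#' Simulate a batch time course
#'
#' Noiseless trajectories: logistic biomass `X(t)`; lipid
#' `L(t) = alpha (X(t) - X0) + beta * integral(X)` with the integral taken
#' by the trapezoid rule on the sampling grid; sugars consumed sequentially
#' in preference order at their stated rates, floored at zero. With
#' `noise_sd > 0`, seeded Gaussian noise is added to every observed series,
#' concentrations are clipped at zero and lipid is clipped at DCW.
#'
#' @param params A [growth_sim_params()].
#' @param times Sampling times, h, strictly increasing from 0.
#' @return A [time_course()].
#' @examples
#' tc <- simulate_timecourse(growth_sim_params(seed = 1), times = seq(0, 120, 15))
#' kinetics(tc)
#' @export
simulate_timecourse <- function(params, times = seq(0, 120, by = 15)) {
  stopifnot(inherits(params, "growth_sim_params"))
  times <- as.numeric(times)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing from 0", call. = FALSE)
  }
  x <- logistic_biomass(times, params$X0, params$K, params$mu)
  l <- params$alpha * (x - params$X0) + params$beta * cumtrapz(times, x)
  if (any(l > x)) {
    stop("parameter error: lipid trajectory exceeds biomass ",
         "(alpha/beta too large for the horizon)", call. = FALSE)
  }
  sugars <- sequential_sugars(times, params$sugar_init, params$sugar_rates)
  if (params$noise_sd > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    n <- length(times)
    x <- pmax(0, x + stats::rnorm(n, 0, params$noise_sd))
    l <- pmax(0, l + stats::rnorm(n, 0, params$noise_sd))
    l <- pmin(l, x)
    sugars[] <- lapply(sugars, function(s)
      pmax(0, s + stats::rnorm(n, 0, params$noise_sd)))
  }
  time_course(times, x, l, sugars)
}

#' Simulate a FAME profile about a mean composition
#'
#' Draws a composition from a Dirichlet distribution centred on a normalized
#' mean profile with the given precision (larger precision = draws closer to
#' the mean), scaled to weight percent. `concentration = Inf` returns the
#' mean profile exactly.
#'
#' @param mean_profile A normalized [fame_profile()] (sums to 100).
#' @param concentration Dirichlet precision, > 0.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [fame_profile()] summing to 100, flagged normalized.
#' @export
simulate_fame_profile <- function(mean_profile, concentration = 500,
                                  seed = NULL) {
  stopifnot(inherits(mean_profile, "fame_profile"))
  if (abs(sum(mean_profile$fractions) - 100) > 0.05) {
    stop("parameter error: mean profile must be normalized (sum to 100)",
         call. = FALSE)
  }
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  p <- mean_profile$fractions / sum(mean_profile$fractions)
  if (is.infinite(concentration)) {
    draw <- p
  } else {
    if (!is.null(seed)) set.seed(seed)
    g <- stats::rgamma(length(p), shape = concentration * p, rate = 1)
    if (sum(g) <= 0) g <- p  # degenerate draw guard for tiny shapes
    draw <- g / sum(g)
  }
  fame_profile(stats::setNames(100 * draw, names(p)),
               sample_id = paste0(mean_profile$sample_id, "_sim"),
               normalized = TRUE)
}

#' Simulate a Nile-red screening table
#'
#' Strain lipid titres are drawn from a two-component Gaussian mixture
#' (an oleaginous high-lipid mode and a non-oleaginous low mode). RFU is an
#' affine gain on lipid plus Gaussian replicate noise whose variance is
#' solved so that the Pearson correlation between per-strain mean RFU (over
#' `n_replicates`) and lipid titre equals `target_r` conditional on the
#' drawn titres:
#' `sigma_rep^2 = n_replicates * gain^2 * var(titre) * (1/r^2 - 1)`,
#' with `var(titre)` the realized variance of the drawn strain titres (so
#' the calibration does not drift with the mixture draw).
#'
#' @param n_strains Number of strains, >= 3.
#' @param target_r Target population correlation; `|target_r|` in (0, 1]
#'   (negative values flip the gain sign; `|r| = 1` gives zero noise).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param n_replicates RFU replicates per strain (default 4).
#' @param p_oleaginous Mixture weight of the high-lipid mode.
#' @param titre_modes,titre_sds Means and standard deviations (g/L) of the
#'   (non-oleaginous, oleaginous) titre modes.
#' @param gain,offset RFU response: `RFU = gain * lipid + offset + noise`.
#' @return A [screening_table()] with lipid titre and content filled in.
#' @export
simulate_screening_table <- function(n_strains, target_r = 0.94, seed = NULL,
                                     n_replicates = 4, p_oleaginous = 0.1,
                                     titre_modes = c(0.35, 1.5),
                                     titre_sds = c(0.1, 0.3),
                                     gain = 1500, offset = 2000) {
  if (n_strains < 3) stop("need at least 3 strains", call. = FALSE)
  if (is.na(target_r) || abs(target_r) > 1 || target_r == 0) {
    stop("parameter error: |target_r| must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- gain * sign(target_r)
  is_ole <- stats::runif(n_strains) < p_oleaginous
  titre <- pmax(0.05, stats::rnorm(n_strains,
                                   mean = titre_modes[is_ole + 1L],
                                   sd = titre_sds[is_ole + 1L]))
  v <- stats::var(titre)
  if (v == 0) stop("parameter error: drawn titres have zero variance",
                   call. = FALSE)
  sigma_rep <- sqrt(n_replicates * gain^2 * v * (1 / target_r^2 - 1))
  rfu <- lapply(titre, function(lt) {
    pmax(0, g * lt + offset + stats::rnorm(n_replicates, 0, sigma_rep))
  })
  dcw <- pmax(titre * 1.2,
              stats::rnorm(n_strains, mean = 4.5, sd = 0.5))
  screening_table(sprintf("S%03d", seq_len(n_strains)), rfu,
                  lipid_titre = titre,
                  lipid_content = 100 * titre / dcw)
}

table1_params <- function() {
  # before/after cultivation means and SDs of a saccharified-hydrolysate
  # nutrient panel; NA after-values are "not detected"
  df <- data.frame(
    analyte = c("glucose", "xylose", "arabinose", "total proteins",
                "total nitrogen", "calcium", "sodium", "magnesium",
                "phosphorous", "potassium", "manganese", "iron",
                "5-HMF", "acetic acid"),
    unit = c("g/L", "g/L", "g/L", "g/L", "g/L", "mg/L", "g/L", "g/L",
             "g/L", "g/L", "mg/L", "mg/L", "g/L", "g/L"),
    before_mean = c(28.05, 18.13, 0.29, 0.33, 0.053, 107, 1.08, 1.53,
                    1.51, 1.53, 0.37, 0.067, 0.013, 0.046),
    before_sd = c(0.01, 0.04, 0.01, 0.02, 0.01, 0.87, 0.15, 0.003,
                  0.001, 0.005, 0.05, 0.009, 0.005, 0.01),
    after_mean = c(NA, 0.05, NA, 0.23, 0.037, 6.3, 0.84, 0.22,
                   0.36, 0.38, 0.24, 0.036, 0.01, NA),
    stringsAsFactors = FALSE)
  df$retention <- df$after_mean / df$before_mean
  df
}

#' Simulate a hydrolysate composition and pretreatment records
#'
#' Before-cultivation concentrations are drawn from truncated normals about
#' the generator's nutrient-panel means; after-cultivation values apply
#' per-analyte retention fractions (so utilization percentages are exact
#' regardless of noise); "not detected" entries stay missing. Pretreatment
#' stream records (acid/alkali liquids and their saccharified solids, with
#' inhibitor levels and the detoxification sugar loss) accompany the
#' composition.
#'
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param sd_scale Multiplier on the panel's standard deviations; 0 yields
#'   the exact means.
#' @return List with elements `composition` (a
#'   [hydrolysate_composition()]) and `pretreatment` (list of
#'   [pretreatment_record()]s).
#' @export
simulate_hydrolysate <- function(seed = NULL, sd_scale = 1) {
  if (sd_scale < 0) stop("sd_scale must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- table1_params()
  before <- pmax(0, stats::rnorm(nrow(p), p$before_mean,
                                 sd_scale * p$before_sd))
  after <- before * p$retention
  comp <- hydrolysate_composition(p$analyte, p$unit, before, after)
  pre <- list(
    pretreatment_record("acid-liquid", 20, sugars_before = 37.38,
                        sugars_after = 31.91,
                        inhibitors = c("acetic acid" = 5.61)),
    pretreatment_record("alkali-liquid", 20, sugars_before = 0.7),
    pretreatment_record("acid-solid-sacch", 20, sugars_before = 7.63,
                        inhibitors = c("acetic acid" = 0.3,
                                       "furfural" = 0.19)),
    pretreatment_record("alkali-solid-sacch", 20, sugars_before = 46.47,
                        inhibitors = c("5-HMF" = 0.013, "furfural" = 0,
                                       "acetic acid" = 0.046))
  )
  list(composition = comp, pretreatment = pre)
}

#' Materialize a demo dataset tree
#'
#' Writes, under `dir`, the CSV inputs a full pipeline run consumes: the
#' as-printed FAME composition tables shipped with the package, the
#' synthetic batch time course whose endpoints match the printed batch
#' summaries, a simulated hydrolysate composition (exact panel means), and
#' a simulated 57-strain screening table.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed for the simulated tables.
#' @return Named character vector of the files written, invisibly.
#' @export
write_demo_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- function(f) system.file("extdata", f, package = "oleofuel")
  files <- c(fame = file.path(dir, "fame_as_psh.csv"),
             timecourse = file.path(dir, "timecourse_as_psh_synthetic.csv"),
             hydrolysate = file.path(dir, "hydrolysate.csv"),
             screening = file.path(dir, "screening.csv"))
  file.copy(ext("fame_as_psh.csv"), files["fame"], overwrite = TRUE)
  file.copy(ext("timecourse_as_psh_synthetic.csv"), files["timecourse"],
            overwrite = TRUE)
  hy <- simulate_hydrolysate(seed = seed, sd_scale = 0)$composition
  utils::write.csv(hy[c("analyte", "unit", "before", "after")],
                   files["hydrolysate"], row.names = FALSE, quote = FALSE)
  write_screening_csv(simulate_screening_table(57, seed = seed),
                      files["screening"])
  invisible(files)
}
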