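#' Construct a batch-cultivation time course
#'
#' Holds sampled trajectories of dry cell weight (DCW), lipid titre and
#' individual sugar concentrations over a batch fermentation.
#'
#' @param times Sampling times in hours; strictly increasing, first = 0.
#' @param dcw Dry cell weight, g/L, one value per time.
#' @param lipid_titre Gravimetric lipid titre, g/L; must not exceed DCW.
#' @param sugars Optional data.frame (or named list) of per-sugar
#'   concentrations in g/L, one column per sugar, one row per time. `NA`
#'   marks an unmeasured sample.
#' @return Object of class `time_course`.
#' @examples
#' time_course(c(0, 24, 48), dcw = c(0.1, 3, 8), lipid_titre = c(0, 1, 4),
#'             sugars = data.frame(glucose = c(30, 22, 10)))
#' @export
time_course <- function(times, dcw, lipid_titre, sugars = NULL) {
  times <- as.numeric(times)
  dcw <- as.numeric(dcw)
  lipid_titre <- as.numeric(lipid_titre)
  n <- length(times)
  if (n < 2) stop("a time course needs at least two samples", call. = FALSE)
  if (times[1] != 0) stop("first sampling time must be 0 h", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (length(dcw) != n || length(lipid_titre) != n) {
    stop("dcw and lipid_titre must have one value per time", call. = FALSE)
  }
  if (any(dcw < 0, na.rm = TRUE) || any(lipid_titre < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (any(lipid_titre > dcw + 1e-9, na.rm = TRUE)) {
    stop("lipid titre exceeds DCW at some sampling time", call. = FALSE)
  }
  if (!is.null(sugars)) {
    sugars <- as.data.frame(sugars)
    if (nrow(sugars) != n) {
      stop("sugar columns must have one value per time", call. = FALSE)
    }
    if (any(unlist(sugars) < 0, na.rm = TRUE)) {
      stop("sugar concentrations must be >= 0", call. = FALSE)
    }
  }
  structure(list(times = times, dcw = dcw, lipid_titre = lipid_titre,
                 sugars = sugars),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Batch time course: %d samples over %g h, %d sugar(s)\n",
              length(x$times), max(x$times),
              if (is.null(x$sugars)) 0L else ncol(x$sugars)))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  df <- data.frame(time_h = x$times, dcw_g_l = x$dcw,
                   lipid_g_l = x$lipid_titre)
  if (!is.null(x$sugars)) {
    sg <- x$sugars
    names(sg) <- paste0(names(sg), "_g_l")
    df <- cbind(df, sg)
  }
  df
}

#' Read / write time-course CSV
#'
#' Dialect: `time_h,dcw_g_l,lipid_g_l,<sugar>_g_l,...` with any number of
#' sugar columns (suffix `_g_l` stripped to form the sugar name).
#'
#' @param path File path.
#' @return `read_timecourse_csv()` a [time_course()]; the writer returns
#'   `path` invisibly.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "dcw_g_l", "lipid_g_l")
  if (!all(need %in% names(df))) {
    stop("time-course CSV needs columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  }
  sugar_cols <- setdiff(names(df), need)
  sugars <- NULL
  if (length(sugar_cols)) {
    sugars <- df[sugar_cols]
    names(sugars) <- sub("_g_l$", "", names(sugars))
  }
  time_course(df$time_h, df$dcw_g_l, df$lipid_g_l, sugars)
}

#' @rdname read_timecourse_csv
#' @param tc A [time_course()].
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Lipid content as percent of dry cell weight
#'
#' @param lipid_titre Lipid concentration, g/L.
#' @param dcw Dry cell weight, g/L, > 0.
#' @return Percent w/w, `100 * lipid_titre / dcw`.
#' @examples
#' lipid_content(7.02, 12.56)  # 55.89
#' @export
lipid_content <- function(lipid_titre, dcw) {
  if (any(dcw <= 0)) stop("DCW must be > 0", call. = FALSE)
  if (any(lipid_titre < 0)) stop("lipid titre must be >= 0", call. = FALSE)
  if (any(lipid_titre > dcw + 1e-9)) {
    stop("lipid titre exceeds DCW", call. = FALSE)
  }
  100 * lipid_titre / dcw
}

#' Volumetric productivity over a time window
#'
#' @param delta_conc Concentration change, g/L.
#' @param delta_t Elapsed time, h, > 0.
#' @return g/L/h.
#' @examples
#' productivity(7.02, 120)  # lipid productivity, 0.0585
#' @export
productivity <- function(delta_conc, delta_t) {
  if (any(delta_t <= 0)) stop("elapsed time must be > 0", call. = FALSE)
  delta_conc / delta_t
}

#' Sugar consumption rate
#'
#' @param initial,final Sugar concentrations, g/L; `final <= initial` for
#'   net consumption (a higher final value warns of net production and
#'   returns the signed rate).
#' @param delta_t Elapsed time, h, > 0.
#' @return g/L/h.
#' @examples
#' consumption_rate(30, 0, 120)  # 0.25
#' @export
consumption_rate <- function(initial, final, delta_t) {
  if (any(delta_t <= 0)) stop("elapsed time must be > 0", call. = FALSE)
  if (any(final > initial)) {
    warning("final concentration exceeds initial: net production",
            call. = FALSE)
  }
  (initial - final) / delta_t
}

#' Percent utilization of an analyte over cultivation
#'
#' `100 (before - after) / before`; shared contract with
#' [detox_loss_percent()], which reports the same quantity for a
#' detoxification step.
#'
#' @param before Concentration before cultivation, > 0.
#' @param after Concentration after cultivation, >= 0.
#' @return Percent.
#' @examples
#' utilization_percent(107, 6.3)  # calcium, 94.11
#' @export
utilization_percent <- function(before, after) {
  if (any(before <= 0)) stop("'before' must be > 0", call. = FALSE)
  if (any(after < 0)) stop("'after' must be >= 0", call. = FALSE)
  100 * (before - after) / before
}

#' @rdname utilization_percent
#' @export
detox_loss_percent <- function(before, after) {
  utilization_percent(before, after)
}

#' Fold change between two positive quantities
#'
#' @param a Numerator value.
#' @param b Denominator value, > 0.
#' @return `a / b`.
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be > 0", call. = FALSE)
  a / b
}

#' Total sugars in a composition
#'
#' @param x Numeric vector of sugar concentrations (g/L), or a
#'   [hydrolysate_composition()] (its before-cultivation sugar entries are
#'   summed).
#' @return g/L.
#' @examples
#' total_sugars(c(28.05, 18.13, 0.29))  # 46.47
#' @export
total_sugars <- function(x) {
  if (inherits(x, "hydrolysate_composition")) {
    x <- x$before_g_l[x$is_sugar]
  }
  sum(x, na.rm = TRUE)
}

#' Single-point HPLC quantification
#'
#' Concentration from a single external standard:
#' `standard_conc * peak_area_sample / peak_area_standard`.
#'
#' @param peak_area_sample,peak_area_standard Peak areas, arbitrary units;
#'   the standard's area must be > 0.
#' @param standard_conc Standard concentration, g/L (default 1.0).
#' @return g/L.
#' @export
hplc_quantify <- function(peak_area_sample, peak_area_standard,
                          standard_conc = 1.0) {
  if (any(peak_area_standard <= 0)) {
    stop("standard peak area must be > 0 (calibration error)", call. = FALSE)
  }
  if (any(peak_area_sample < 0)) {
    stop("sample peak area must be >= 0", call. = FALSE)
  }
  standard_conc * peak_area_sample / peak_area_standard
}

#' Shell-to-biodiesel mass-balance ledger
#'
#' Chains the stages of the process on a per-litre basis: shell powder
#' loading, dry cell weight, extracted lipid, and FAME biodiesel after
#' transesterification, with per-stage yield ratios.
#'
#' @param ps_loading Shell powder loading, percent w/v (g per 100 mL, so
#'   `10 * ps_loading` g/L enter the balance).
#' @param dcw Dry cell weight produced, g/L.
#' @param lipid Lipid titre, g/L; must not exceed `dcw`.
#' @param trans_eff Transesterification efficiency as a fraction in `[0, 1]`.
#' @return Object of class `mass_balance`: data.frame of stages with
#'   `amount_g_l` and `yield_pct_of_previous`.
#' @examples
#' mass_balance(20, 12.8, 6.8, 0.9177)
#' @export
mass_balance <- function(ps_loading, dcw, lipid, trans_eff) {
  if (any(c(ps_loading, dcw, lipid) < 0)) {
    stop("loadings and titres must be >= 0", call. = FALSE)
  }
  if (trans_eff < 0 || trans_eff > 1) {
    stop("transesterification efficiency must lie in [0, 1]", call. = FALSE)
  }
  if (lipid > dcw + 1e-9) stop("lipid titre exceeds DCW", call. = FALSE)
  shells_g_l <- 10 * ps_loading
  biodiesel <- estimate_biodiesel_mass(lipid, trans_eff)
  amounts <- c(shells = shells_g_l, dcw = dcw, lipid = lipid,
               biodiesel = biodiesel)
  yields <- c(NA, 100 * amounts[-1] / amounts[-length(amounts)])
  structure(data.frame(stage = names(amounts), amount_g_l = unname(amounts),
                       yield_pct_of_previous = unname(yields),
                       stringsAsFactors = FALSE),
            class = c("mass_balance", "data.frame"))
}

#' @export
print.mass_balance <- function(x, ...) {
  cat("Process mass balance (per litre basis)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Endpoint kinetics of a batch time course
#'
#' Computes biomass and lipid productivities, final lipid content and
#' per-sugar consumption rates over a window of the time course. The default
#' window is the full course (endpoint-based rates, the convention used for
#' 120-h batch figures); `method = "max-slope"` instead reports the maximum
#' rate over adjacent sampling intervals.
#'
#' @param tc A [time_course()].
#' @param window Length-2 numeric `(t_start, t_end)` in hours; defaults to
#'   the full course. Both must be sampling times.
#' @param initial_sugars Named vector of medium recipe concentrations (g/L),
#'   used for any sugar whose value at `t_start` is missing.
#' @param method `"endpoint"` (default) or `"max-slope"`.
#' @return Object of class `kinetics_result`: biomass and lipid
#'   productivities (g/L/h), lipid content (% w/w at `t_end`), per-sugar
#'   consumption rates (g/L/h) and the window used.
#' @examples
#' tc <- time_course(c(0, 60, 120), dcw = c(0.1, 8, 12.56),
#'                   lipid_titre = c(0, 3, 7.02),
#'                   sugars = data.frame(glucose = c(30, 12, 0)))
#' kinetics(tc)
#' @export
kinetics <- function(tc, window = NULL, initial_sugars = NULL,
                     method = c("endpoint", "max-slope")) {
  stopifnot(inherits(tc, "time_course"))
  method <- match.arg(method)
  if (is.null(window)) window <- range(tc$times)
  i0 <- match(window[1], tc$times)
  i1 <- match(window[2], tc$times)
  if (is.na(i0) || is.na(i1) || i1 <= i0) {
    stop("window endpoints must be sampling times with t_start < t_end",
         call. = FALSE)
  }
  dt <- tc$times[i1] - tc$times[i0]
  if (method == "endpoint") {
    bp <- productivity(tc$dcw[i1] - tc$dcw[i0], dt)
    lp <- productivity(tc$lipid_titre[i1] - tc$lipid_titre[i0], dt)
  } else {
    idx <- i0:(i1 - 1)
    dts <- diff(tc$times)[idx]
    bp <- max(diff(tc$dcw)[idx] / dts)
    lp <- max(diff(tc$lipid_titre)[idx] / dts)
  }
  rates <- numeric(0)
  if (!is.null(tc$sugars)) {
    rates <- vapply(names(tc$sugars), function(s) {
      s0 <- tc$sugars[[s]][i0]
      if (is.na(s0) && !is.null(initial_sugars) && s %in% names(initial_sugars)) {
        s0 <- initial_sugars[[s]]
      }
      s1 <- tc$sugars[[s]][i1]
      if (is.na(s0) || is.na(s1)) return(NA_real_)
      consumption_rate(s0, s1, dt)
    }, 1.0)
  }
  structure(list(biomass_productivity = bp,
                 lipid_productivity = lp,
                 lipid_content = lipid_content(tc$lipid_titre[i1], tc$dcw[i1]),
                 consumption_rate = rates,
                 window = c(t_start = tc$times[i0], t_end = tc$times[i1]),
                 method = method),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("Batch kinetics over [%g, %g] h (%s)\n",
              x$window[1], x$window[2], x$method))
  cat(sprintf("  biomass productivity %.4f g/L/h\n", x$biomass_productivity))
  cat(sprintf("  lipid productivity   %.4f g/L/h\n", x$lipid_productivity))
  cat(sprintf("  lipid content        %.2f %% w/w\n", x$lipid_content))
  for (s in names(x$consumption_rate)) {
    cat(sprintf("  %s consumption %.4f g/L/h\n", s, x$consumption_rate[[s]]))
  }
  invisible(x)
}
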