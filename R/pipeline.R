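#' Pipeline configuration
#'
#' Collects the inputs and options of a full analysis run. Any of the four
#' input tables may be omitted; the corresponding stage is skipped with a
#' warning recorded in the report.
#'
#' @param fame,timecourse,hydrolysate,screening Paths to the CSV inputs
#'   (dialects documented at [read_fame_csv()], [read_timecourse_csv()],
#'   [read_hydrolysate_csv()], [read_screening_csv()]), or `NULL`.
#' @param normalize Normalize the FAME profile to 100% before property math
#'   (default `FALSE`: use the composition as printed).
#' @param correlations Cetane-number route, see [fuel_correlations()].
#' @param standard Headline fuel standard for the compliance verdict.
#' @param window Optional `(t_start, t_end)` h for [kinetics()].
#' @param initial_sugars Named vector of medium-recipe sugar concentrations
#'   (g/L) used when the time course lacks a t = 0 sugar sample.
#' @param seed Integer seed for any stochastic stage.
#' @param out_dir Optional output directory for [render_report()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fame = NULL, timecourse = NULL,
                            hydrolysate = NULL, screening = NULL,
                            normalize = FALSE,
                            correlations = c("per-species", "du-regression"),
                            standard = c("EN14214", "ASTMD6751", "IS15607"),
                            window = NULL, initial_sugars = NULL,
                            seed = 1L, out_dir = NULL) {
  correlations <- match.arg(correlations)
  standard <- match.arg(standard)
  for (p in c(fame, timecourse, hydrolysate, screening)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(fame = fame, timecourse = timecourse,
                 hydrolysate = hydrolysate, screening = screening,
                 normalize = isTRUE(normalize), correlations = correlations,
                 standard = standard, window = window,
                 initial_sugars = initial_sugars, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, for whichever inputs the configuration provides:
#' screening ranking and RFU-lipid correlation; batch kinetics;
#' hydrolysate utilization accounting; FAME fuel-property estimation with
#' compliance verdicts against all three encoded standards. The run is
#' deterministic given the configuration (including its seed).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: list with `version`, `config`
#'   echo, `warnings`, and per-stage outputs under `stages`.
#' @examples
#' dir <- tempfile()
#' write_demo_fixtures(dir, seed = 1)
#' cfg <- pipeline_config(fame = file.path(dir, "fame_as_psh.csv"),
#'                        timecourse = file.path(dir,
#'                          "timecourse_as_psh_synthetic.csv"))
#' run_pipeline(cfg)$stages$kinetics$lipid_content
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  stages <- list()

  if (!is.null(config$screening)) {
    tab <- read_screening_csv(config$screening)
    corr <- NULL
    if (sum(!is.na(tab$lipid_titre)) >= 3) {
      corr <- rfu_lipid_correlation(tab)
    } else {
      note("screening: < 3 strains with gravimetric lipid; correlation skipped")
    }
    stages$screening <- list(ranking = rank_by_rfu(tab), correlation = corr)
  }

  if (!is.null(config$timecourse)) {
    tc <- read_timecourse_csv(config$timecourse)
    k <- kinetics(tc, window = config$window,
                  initial_sugars = config$initial_sugars)
    stages$kinetics <- unclass(k)
  }

  if (!is.null(config$hydrolysate)) {
    hc <- read_hydrolysate_csv(config$hydrolysate)
    stages$hydrolysate <- list(utilization = utilization_table(hc),
                               total_sugars = total_sugars(hc))
  }

  if (!is.null(config$fame)) {
    prof <- tryCatch(read_fame_csv(config$fame), error = function(e) e)
    if (inherits(prof, "error") || length(prof$fractions) == 0 ||
        sum(prof$fractions) <= 0) {
      note(paste0("fame: empty or unreadable profile table; ",
                  "property stage skipped"))
    } else {
      tot <- sum(prof$fractions)
      if (abs(tot - 100) > 0.05 && !config$normalize) {
        note(sprintf(paste0("fame: as-printed profile total is %.2f%%, not ",
                            "100%%; properties computed on the raw ",
                            "composition (set normalize for the closed ",
                            "composition)"), tot))
      }
      rep <- fuel_property_report(prof, method = config$correlations,
                                  normalize = config$normalize)
      comp <- lapply(c(EN14214 = "EN14214", ASTMD6751 = "ASTMD6751",
                       IS15607 = "IS15607"), function(s) {
        v <- evaluate_standards(rep, s)
        list(overall = attr(v, "overall"), table = as.data.frame(v))
      })
      stages$fame <- list(properties = unclass(rep), compliance = comp)
    }
  }

  structure(list(version = as.character(utils::packageVersion("oleofuel")),
                 config = unclass(config), warnings = warnings,
                 stages = stages),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("oleofuel run report (v%s): stages %s\n", x$version,
              paste(names(x$stages), collapse = ", ")))
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  if (!is.null(x$stages$kinetics)) {
    cat(sprintf("kinetics: lipid %.4f g/L/h, biomass %.4f g/L/h, content %.2f%%\n",
                x$stages$kinetics$lipid_productivity,
                x$stages$kinetics$biomass_productivity,
                x$stages$kinetics$lipid_content))
  }
  if (!is.null(x$stages$fame)) {
    p <- x$stages$fame$properties
    cat(sprintf("fuel properties (%s): CN %.4g, IV %.4g, KV %.4g, CFPP %.4g\n",
                p$method, p$cn, p$iv, p$kv40, p$cfpp))
  }
  invisible(x)
}

#' Render a run report
#'
#' Serializes a [run_pipeline()] report. JSON keeps full numeric precision
#' and round-trips losslessly; markdown is a human summary whose property
#' table carries the limits and verdicts of all three standards; csv is a
#' flat one-row file of the estimated fuel properties.
#'
#' @param report A `run_report`.
#' @param format `"json"`, `"markdown"` or `"csv"`.
#' @param path Output file; defaults to `report.<ext>` under the config's
#'   `out_dir` (or the working directory).
#' @return The output path, invisibly.
#' @export
render_report <- function(report, format = c("json", "markdown", "csv"),
                          path = NULL) {
  stopifnot(inherits(report, "run_report"))
  format <- match.arg(format)
  if (is.null(path)) {
    dir <- report$config$out_dir
    if (is.null(dir)) dir <- "."
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, paste0("report.",
                                  c(json = "json", markdown = "md",
                                    csv = "csv")[format]))
  }
  if (format == "json") {
    json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE, null = "null",
                             dataframe = "rows")
    writeLines(json, path)
  } else if (format == "csv") {
    if (is.null(report$stages$fame)) {
      stop("no fuel-property stage in this report", call. = FALSE)
    }
    p <- report$stages$fame$properties
    df <- data.frame(p[c("sample_id", "sv", "iv", "cn", "hhv", "density",
                         "kv40", "cfpp", "du", "lcsf", "method",
                         "normalized_input")], stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(report_markdown(report), path)
  }
  invisible(path)
}

fmt4 <- function(x) formatC(x, digits = 4, format = "fg", flag = "#")

report_markdown <- function(report) {
  out <- c(sprintf("# oleofuel run report (v%s)", report$version), "")
  if (length(report$warnings)) {
    out <- c(out, "## Warnings", "", paste("-", report$warnings), "")
  }
  k <- report$stages$kinetics
  if (!is.null(k)) {
    out <- c(out, "## Batch kinetics", "",
             sprintf("- biomass productivity: %s g/L/h",
                     fmt4(k$biomass_productivity)),
             sprintf("- lipid productivity: %s g/L/h",
                     fmt4(k$lipid_productivity)),
             sprintf("- lipid content: %s %% w/w", fmt4(k$lipid_content)))
    for (s in names(k$consumption_rate)) {
      out <- c(out, sprintf("- %s consumption rate: %s g/L/h", s,
                            fmt4(k$consumption_rate[[s]])))
    }
    out <- c(out, "")
  }
  h <- report$stages$hydrolysate
  if (!is.null(h)) {
    out <- c(out, "## Hydrolysate accounting", "",
             sprintf("- total sugars before cultivation: %s g/L",
                     fmt4(h$total_sugars)),
             "", "| analyte | before (g/L) | after (g/L) | utilization (%) |",
             "|---|---|---|---|")
    u <- h$utilization
    out <- c(out, sprintf("| %s | %s | %s | %s |", u$analyte,
                          fmt4(u$before_g_l), fmt4(u$after_g_l),
                          fmt4(u$utilization_pct)), "")
  }
  f <- report$stages$fame
  if (!is.null(f)) {
    p <- f$properties
    out <- c(out, "## Biodiesel properties and standards", "",
             sprintf("Sample `%s`, %s CN route, %s composition.",
                     p$sample_id, p$method,
                     if (p$normalized_input) "normalized" else "as-printed"),
             "",
             "| property | value | EN 14214 | ASTM D6751 | IS 15607 |",
             "|---|---|---|---|---|")
    lim_str <- function(tab, prop) {
      i <- match(prop, tab$property)
      if (is.na(i) || tab$verdict[i] == "not-specified") return("-")
      lo <- tab$min[i]
      hi <- tab$max[i]
      rng <- if (!is.na(lo) && !is.na(hi)) sprintf("%g-%g", lo, hi)
      else if (!is.na(lo)) sprintf(">=%g", lo) else sprintf("<=%g", hi)
      sprintf("%s (%s)", rng, tab$verdict[i])
    }
    props <- c(sv = "SV (mg KOH/g)", iv = "IV (g I2/100 g)", cn = "CN",
               hhv = "HHV (MJ/kg)", density = "density (g/cm^3)",
               kv40 = "KV40 (mm^2/s)", cfpp = "CFPP (degC)")
    for (key in names(props)) {
      out <- c(out, sprintf("| %s | %s | %s | %s | %s |", props[[key]],
                            fmt4(p[[key]]),
                            lim_str(f$compliance$EN14214$table, key),
                            lim_str(f$compliance$ASTMD6751$table, key),
                            lim_str(f$compliance$IS15607$table, key)))
    }
    out <- c(out, "",
             sprintf("Overall: EN 14214 %s, ASTM D6751 %s, IS 15607 %s.",
                     f$compliance$EN14214$overall,
                     f$compliance$ASTMD6751$overall,
                     f$compliance$IS15607$overall), "")
  }
  s <- report$stages$screening
  if (!is.null(s)) {
    out <- c(out, "## Screening", "",
             sprintf("- %d strains ranked by mean RFU; top strain %s",
                     nrow(s$ranking), s$ranking$strain_id[1]))
    if (!is.null(s$correlation)) {
      out <- c(out, sprintf(
        "- RFU vs gravimetric lipid: Pearson r = %s (n = %d, p = %.3g)",
        fmt4(s$correlation$r), s$correlation$n, s$correlation$p_value))
    }
    out <- c(out, "")
  }
  out
}

#' Parse a JSON run report back into a list
#'
#' @param path Path written by [render_report()] with `format = "json"`.
#' @return The report as a plain list.
#' @export
parse_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
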