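#' Hydrolysate composition before and after cultivation
#'
#' Tabulates analyte concentrations in a lignocellulosic hydrolysate before
#' inoculation and after the batch. Mixed units (g/L and mg/L) are carried
#' per analyte and converted internally to g/L; "not detected" entries are
#' explicit missing values (`NA`), not zeros, and are excluded from
#' utilization arithmetic.
#'
#' @param analyte Character vector of analyte names.
#' @param unit Per-analyte unit, `"g/L"` or `"mg/L"`.
#' @param before,after Concentrations in `unit`; `NA` = not detected.
#' @param sugars Character vector naming which analytes are fermentable
#'   sugars (used by [total_sugars()]).
#' @return Object of class `hydrolysate_composition`: data.frame with the
#'   original columns plus `before_g_l`, `after_g_l`, `is_sugar`.
#' @export
hydrolysate_composition <- function(analyte, unit, before, after,
                                    sugars = c("glucose", "xylose",
                                               "arabinose")) {
  analyte <- as.character(analyte)
  unit <- as.character(unit)
  if (anyDuplicated(tolower(analyte))) {
    stop("duplicate analyte names", call. = FALSE)
  }
  if (!all(unit %in% c("g/L", "mg/L"))) {
    stop("units must be 'g/L' or 'mg/L'", call. = FALSE)
  }
  before <- as.numeric(before)
  after <- as.numeric(after)
  if (any(c(before, after) < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  f <- ifelse(unit == "mg/L", 1e-3, 1)
  structure(data.frame(analyte = analyte, unit = unit, before = before,
                       after = after, before_g_l = before * f,
                       after_g_l = after * f,
                       is_sugar = tolower(analyte) %in% tolower(sugars),
                       stringsAsFactors = FALSE),
            class = c("hydrolysate_composition", "data.frame"))
}

#' Read a hydrolysate composition CSV
#'
#' Dialect: columns `analyte,unit,before,after`; empty cells are "not
#' detected" and become `NA`.
#'
#' @param path File path.
#' @inheritParams hydrolysate_composition
#' @return A [hydrolysate_composition()].
#' @export
read_hydrolysate_csv <- function(path, sugars = c("glucose", "xylose",
                                                  "arabinose")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "ND", "-"))
  need <- c("analyte", "unit", "before", "after")
  if (!all(need %in% names(df))) {
    stop("hydrolysate CSV needs columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  }
  hydrolysate_composition(df$analyte, df$unit, df$before, df$after,
                          sugars = sugars)
}

#' Per-analyte utilization over cultivation
#'
#' Applies [utilization_percent()] to every analyte with both a before- and
#' an after-cultivation measurement; analytes with a missing value (not
#' detected) are reported as `NA` unless `detection_limit` substitutes a
#' value for missing after-entries.
#'
#' @param hc A [hydrolysate_composition()].
#' @param detection_limit Optional concentration (g/L) substituted for
#'   missing after-cultivation entries; default `NULL` leaves them excluded.
#' @return Data.frame with columns `analyte`, `before_g_l`, `after_g_l`,
#'   `utilization_pct`.
#' @export
utilization_table <- function(hc, detection_limit = NULL) {
  stopifnot(inherits(hc, "hydrolysate_composition"))
  after <- hc$after_g_l
  if (!is.null(detection_limit)) {
    after[is.na(after)] <- as.numeric(detection_limit)
  }
  util <- ifelse(!is.na(hc$before_g_l) & hc$before_g_l > 0 & !is.na(after),
                 100 * (hc$before_g_l - after) / hc$before_g_l, NA_real_)
  data.frame(analyte = hc$analyte, before_g_l = hc$before_g_l,
             after_g_l = after, utilization_pct = util,
             stringsAsFactors = FALSE)
}

#' @export
print.hydrolysate_composition <- function(x, ...) {
  cat(sprintf("Hydrolysate composition: %d analytes (%d sugars)\n",
              nrow(x), sum(x$is_sugar)))
  print.data.frame(x[c("analyte", "unit", "before", "after")],
                   row.names = FALSE)
  invisible(x)
}

#' Pretreatment stream record
#'
#' Describes one pretreatment/saccharification stream: total fermentable
#' sugars before and after detoxification and the inhibitor levels.
#'
#' @param stream One of `"acid-liquid"`, `"alkali-liquid"`,
#'   `"acid-solid-sacch"`, `"alkali-solid-sacch"`.
#' @param solids_loading Percent w/v solids in the pretreatment.
#' @param sugars_before,sugars_after Total sugars, g/L, before and after
#'   detoxification (`sugars_after = NA` if the stream is not detoxified).
#' @param inhibitors Named numeric vector (g/L), e.g. 5-HMF, furfural,
#'   acetic acid.
#' @return Object of class `pretreatment_record`.
#' @export
pretreatment_record <- function(stream, solids_loading, sugars_before,
                                sugars_after = NA_real_,
                                inhibitors = numeric(0)) {
  stream <- match.arg(stream, c("acid-liquid", "alkali-liquid",
                                "acid-solid-sacch", "alkali-solid-sacch"))
  if (solids_loading < 0 || sugars_before < 0) {
    stop("loading and sugar totals must be >= 0", call. = FALSE)
  }
  if (!is.na(sugars_after) && sugars_after > sugars_before) {
    stop("detoxification cannot increase total sugars", call. = FALSE)
  }
  structure(list(stream = stream, solids_loading = solids_loading,
                 sugars_before = sugars_before, sugars_after = sugars_after,
                 inhibitors = inhibitors),
            class = "pretreatment_record")
}

#' @export
print.pretreatment_record <- function(x, ...) {
  cat(sprintf("Pretreatment stream '%s' (%g%% w/v solids)\n",
              x$stream, x$solids_loading))
  cat(sprintf("  total sugars %.2f g/L", x$sugars_before))
  if (!is.na(x$sugars_after)) {
    cat(sprintf(" -> %.2f g/L after detox (%.2f%% loss)",
                x$sugars_after,
                detox_loss_percent(x$sugars_before, x$sugars_after)))
  }
  cat("\n")
  if (length(x$inhibitors)) {
    cat("  inhibitors (g/L):",
        paste(sprintf("%s %.3g", names(x$inhibitors), x$inhibitors),
              collapse = ", "), "\n")
  }
  invisible(x)
}
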