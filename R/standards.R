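#' Fuel-standard limit sets
#'
#' Per-property bounds for EN 14214, ASTM D6751 and IS 15607, shipped as a
#' versioned tab-separated table (see
#' `system.file("extdata", "standards.tsv", package = "oleofuel")`). Two
#' limit sets are available: `"as-printed"` (default) transcribes a widely
#' circulated comparison grid whose CN and KV columns conflict with the
#' official standard documents, and `"literature"` carries the official
#' published limits. The conflict is retained deliberately so published
#' comparisons can be reproduced as printed.
#'
#' @param set `"as-printed"` or `"literature"`.
#' @param path Optional path to an alternative limits table in the same
#'   format.
#' @return A data.frame with columns `standard`, `property`, `min`, `max`
#'   (NA = unbounded), of class `fuel_standards`.
#' @export
fuel_standards <- function(set = c("as-printed", "literature"), path = NULL) {
  set <- match.arg(set)
  if (is.null(path)) {
    path <- system.file("extdata", "standards.tsv", package = "oleofuel")
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "numeric", "numeric"))
  df <- df[df$set == set, c("standard", "property", "min", "max")]
  if (nrow(df) == 0) stop("unknown limit set: ", set, call. = FALSE)
  bad <- !is.na(df$min) & !is.na(df$max) & df$min > df$max
  if (any(bad)) stop("limits table has min > max", call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("fuel_standards", "data.frame"))
}

#' Check a property report against a fuel standard
#'
#' Compares each estimated property with the chosen standard's limits and
#' returns a per-property verdict (`"pass"`, `"fail"`, or
#' `"not-specified"` when the standard designates no limit). The overall
#' verdict passes iff no property fails.
#'
#' @param report A [fuel_property_report()].
#' @param standard One of `"EN14214"`, `"ASTMD6751"`, `"IS15607"`.
#' @param limits A [fuel_standards()] table.
#' @return A data.frame of class `compliance_verdict` with columns
#'   `property`, `value`, `min`, `max`, `verdict` and attribute
#'   `overall` (`"pass"`/`"fail"`).
#' @examples
#' p <- fame_profile(c("C16:0" = 30, "C18:1" = 55, "C18:2" = 15))
#' evaluate_standards(fuel_property_report(p), "IS15607")
#' @export
evaluate_standards <- function(report,
                               standard = c("EN14214", "ASTMD6751", "IS15607"),
                               limits = fuel_standards()) {
  stopifnot(inherits(report, "fuel_property_report"))
  standard <- match.arg(standard)
  lim <- limits[limits$standard == standard, , drop = FALSE]
  if (nrow(lim) == 0) {
    stop("standard not present in limits table: ", standard, call. = FALSE)
  }
  props <- c("iv", "cn", "hhv", "density", "kv40", "cfpp")
  vals <- unlist(report[props])
  if (any(!is.finite(vals))) {
    stop("report contains non-finite property values", call. = FALSE)
  }
  out <- data.frame(property = props, value = unname(vals),
                    min = NA_real_, max = NA_real_,
                    verdict = "not-specified", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lim))) {
    j <- match(lim$property[i], out$property)
    if (is.na(j)) next
    out$min[j] <- lim$min[i]
    out$max[j] <- lim$max[i]
    ok <- (is.na(lim$min[i]) || out$value[j] >= lim$min[i]) &&
      (is.na(lim$max[i]) || out$value[j] <= lim$max[i])
    out$verdict[j] <- if (ok) "pass" else "fail"
  }
  structure(out, standard = standard,
            overall = if (any(out$verdict == "fail")) "fail" else "pass",
            class = c("compliance_verdict", "data.frame"))
}

#' @export
print.compliance_verdict <- function(x, ...) {
  cat(sprintf("Compliance with %s: %s\n", attr(x, "standard"),
              toupper(attr(x, "overall"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
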