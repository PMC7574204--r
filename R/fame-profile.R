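#' Parse a fatty-acid species label
#'
#' Fatty-acid (methyl-ester) species are written in the field's shorthand
#' `"Cn:D"`, e.g. `"C18:1"` for oleate: `n` carbons in the acyl chain and
#' `D` double bonds.
#'
#' @param label Character vector of `"Cn:D"` labels.
#' @return A data.frame with columns `label`, `carbons`, `double_bonds`.
#' @examples
#' parse_species(c("C16:0", "C18:1"))
#' @export
parse_species <- function(label) {
  label <- trimws(as.character(label))
  m <- regmatches(label, regexec("^C([0-9]+):([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid species label(s): ", paste(label[bad], collapse = ", "),
         " (expected \"Cn:D\", e.g. \"C18:1\")", call. = FALSE)
  }
  carbons <- vapply(m, function(x) as.integer(x[2]), 1L)
  dbl <- vapply(m, function(x) as.integer(x[3]), 1L)
  validate_species(carbons, dbl)
  data.frame(label = species_label(carbons, dbl), carbons = carbons,
             double_bonds = dbl, stringsAsFactors = FALSE)
}

#' @rdname parse_species
#' @param carbons,double_bonds Integer vectors describing species.
#' @export
species_label <- function(carbons, double_bonds) {
  sprintf("C%d:%d", as.integer(carbons), as.integer(double_bonds))
}

validate_species <- function(carbons, double_bonds) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  ok <- !is.na(carbons) & !is.na(double_bonds) &
    carbons >= 4L & double_bonds >= 0L &
    double_bonds <= floor((carbons - 2L) / 2L)
  if (!all(ok)) {
    stop("invalid fatty-acid species: carbons must be >= 4 and double bonds ",
         "between 0 and floor((carbons - 2)/2)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Molecular weight of a fatty-acid methyl ester
#'
#' The methyl ester of an acyl chain with `n` carbons and `D` double bonds
#' has formula C(n+1) H(2n+2-2D) O2; the molecular weight is assembled from
#' atomic masses (C 12.011, H 1.008, O 15.999 g/mol). These per-species
#' weights are the denominators of the saponification- and iodine-value
#' sums.
#'
#' @param carbons Integer chain length(s), >= 4.
#' @param double_bonds Integer double-bond count(s), >= 0.
#' @return Numeric vector of molecular weights in g/mol.
#' @examples
#' methyl_ester_mw(16, 0)  # methyl palmitate, 270.46
#' methyl_ester_mw(18, 1)  # methyl oleate, 296.50
#' @export
methyl_ester_mw <- function(carbons, double_bonds) {
  validate_species(carbons, double_bonds)
  n <- as.numeric(carbons)
  d <- as.numeric(double_bonds)
  12.011 * (n + 1) + 1.008 * (2 * n + 2 - 2 * d) + 31.998
}

#' Construct a FAME weight-percent profile
#'
#' A `fame_profile` holds the GC-resolved composition of a transesterified
#' lipid sample: weight percent per fatty-acid methyl-ester species. Profiles
#' as printed in composition tables frequently do not sum to exactly 100
#' (minor species are dropped); the object therefore carries a `normalized`
#' flag and [normalize_profile()] rescales on request.
#'
#' @param fractions Named numeric vector; names are `"Cn:D"` species labels,
#'   values weight percent (>= 0). Duplicate species are an error.
#' @param sample_id Character scalar identifying the sample.
#' @param normalized Logical; `TRUE` asserts the fractions already sum to 100.
#' @return An object of class `fame_profile`.
#' @examples
#' fame_profile(c("C16:0" = 28.85, "C18:1" = 52.58, "C18:2" = 12.45))
#' @export
fame_profile <- function(fractions, sample_id = "sample", normalized = FALSE) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("'fractions' must be a named numeric vector of \"Cn:D\" species",
         call. = FALSE)
  }
  fractions <- vapply(fractions, as.numeric, 1.0)
  sp <- parse_species(names(fractions))
  names(fractions) <- sp$label
  if (anyDuplicated(names(fractions))) {
    stop("duplicate species in profile: ",
         paste(unique(names(fractions)[duplicated(names(fractions))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(fractions < 0)) stop("weight percents must be >= 0", call. = FALSE)
  tot <- sum(fractions)
  if (!normalized && tot > 100 + 0.5) {
    stop(sprintf("profile sums to %.2f%% (> 100 + 0.5 tolerance)", tot),
         call. = FALSE)
  }
  if (normalized && abs(tot - 100) > 0.05) {
    stop(sprintf("profile flagged normalized but sums to %.4f%%", tot),
         call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id)[1],
                 fractions = fractions,
                 normalized = isTRUE(normalized),
                 metadata = list()),
            class = "fame_profile")
}

#' @export
print.fame_profile <- function(x, ...) {
  cat(sprintf("FAME profile '%s' (%d species, total %.2f%%%s)\n",
              x$sample_id, length(x$fractions), sum(x$fractions),
              if (x$normalized) ", normalized" else ""))
  print(round(x$fractions, 3))
  invisible(x)
}

#' @export
as.data.frame.fame_profile <- function(x, ...) {
  sp <- parse_species(names(x$fractions))
  data.frame(sample_id = x$sample_id, species = sp$label,
             carbons = sp$carbons, double_bonds = sp$double_bonds,
             wt_percent = unname(x$fractions), stringsAsFactors = FALSE)
}

#' Rescale a FAME profile to sum to 100 percent
#'
#' Printed FAME tables often total less than 100% because trace species are
#' omitted. Property correlations can be applied to the raw (as-printed)
#' composition or to the closed (normalized) composition; this function
#' produces the latter. The pre-normalization total is kept in
#' `$metadata$raw_total`.
#'
#' @param profile A [fame_profile()].
#' @return A `fame_profile` whose fractions sum to exactly 100, flagged
#'   `normalized`. Idempotent.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  tot <- sum(profile$fractions)
  if (tot <= 0) stop("degenerate profile: all weight percents are zero",
                     call. = FALSE)
  out <- profile
  if (is.null(out$metadata$raw_total)) out$metadata$raw_total <- tot
  out$fractions <- profile$fractions * (100 / tot)
  out$normalized <- TRUE
  out
}

#' Saturation-class summary of a FAME profile
#'
#' Partitions the composition into saturated (SFA, zero double bonds),
#' monounsaturated (MUFA, one) and polyunsaturated (PUFA, two or more)
#' totals and derives the two scalar predictors used by the fuel-property
#' regressions:
#' \describe{
#'   \item{du}{degree of unsaturation, `(MUFA + 2 PUFA)/100`, in
#'     mass-fraction units (typical biodiesels fall in 0.5--2).}
#'   \item{lcsf}{long-chain saturation factor,
#'     `0.1 N(C16:0) + 0.5 N(C18:0) + 1 N(C20:0) + 1.5 N(C22:0) + 2 N(C24:0)`
#'     on the weight percents.}
#' }
#'
#' @param profile A [fame_profile()].
#' @return An object of class `class_summary`: list with `sfa`, `mufa`,
#'   `pufa` (percent), `du`, `lcsf`, and `total` (sum of the input percents).
#' @examples
#' class_summary(fame_profile(c("C18:1" = 100)))
#' @export
class_summary <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  sp <- parse_species(names(profile$fractions))
  ni <- profile$fractions
  sfa <- sum(ni[sp$double_bonds == 0L])
  mufa <- sum(ni[sp$double_bonds == 1L])
  pufa <- sum(ni[sp$double_bonds >= 2L])
  lcsf_w <- c("C16:0" = 0.1, "C18:0" = 0.5, "C20:0" = 1, "C22:0" = 1.5,
              "C24:0" = 2)
  present <- intersect(names(lcsf_w), names(ni))
  structure(list(sfa = sfa, mufa = mufa, pufa = pufa,
                 du = (mufa + 2 * pufa) / 100,
                 lcsf = sum(lcsf_w[present] * ni[present]),
                 total = sum(ni)),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("SFA %.2f%%  MUFA %.2f%%  PUFA %.2f%%  (total %.2f%%)\n",
              x$sfa, x$mufa, x$pufa, x$total))
  cat(sprintf("DU %.4f (mass-fraction)  LCSF %.4f\n", x$du, x$lcsf))
  invisible(x)
}

#' Normalize TLC lipid-class intensities to percentages
#'
#' Converts four densitometric band intensities (triacylglycerol,
#' diacylglycerol, monoacylglycerol, free fatty acid) into percent of total
#' lipid signal.
#'
#' @param tag,dag,mag,ffa Non-negative band intensities (arbitrary units).
#' @return An object of class `lipid_class_profile`: list of `tag`, `dag`,
#'   `mag`, `ffa` percentages summing to 100.
#' @examples
#' normalize_lipid_classes(67.92, 10.29, 12.11, 9.67)
#' @export
normalize_lipid_classes <- function(tag, dag, mag, ffa) {
  v <- c(tag = tag, dag = dag, mag = mag, ffa = ffa)
  if (any(v < 0)) stop("intensities must be >= 0", call. = FALSE)
  tot <- sum(v)
  if (tot <= 0) stop("degenerate input: all intensities are zero",
                     call. = FALSE)
  structure(as.list(100 * v / tot), class = "lipid_class_profile")
}

#' @export
print.lipid_class_profile <- function(x, ...) {
  cat(sprintf("TAG %.2f%%  DAG %.2f%%  MAG %.2f%%  FFA %.2f%%\n",
              x$tag, x$dag, x$mag, x$ffa))
  invisible(x)
}

#' Read / write FAME profile CSV
#'
#' One dialect: columns `species` (`"Cn:D"`), optional `label`, and
#' `wt_percent`. Duplicate species rows are rejected.
#'
#' @param path File path.
#' @param sample_id Sample identifier for the returned profile; defaults to
#'   the file base name.
#' @return `read_fame_csv()` a [fame_profile()]; `write_fame_csv()` the path,
#'   invisibly.
#' @export
read_fame_csv <- function(path, sample_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "wt_percent") %in% names(df))) {
    stop("FAME CSV needs columns 'species' and 'wt_percent': ", path,
         call. = FALSE)
  }
  if (anyDuplicated(df$species)) {
    stop("duplicate species rows in ", path, call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  fame_profile(stats::setNames(df$wt_percent, df$species),
               sample_id = sample_id)
}

#' @rdname read_fame_csv
#' @param profile A [fame_profile()] to serialize.
#' @export
write_fame_csv <- function(profile, path) {
  stopifnot(inherits(profile, "fame_profile"))
  df <- as.data.frame(profile)
  utils::write.csv(df[c("species", "wt_percent")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
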