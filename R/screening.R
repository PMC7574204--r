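#' Nile-red screening table
#'
#' Per-strain records of microwave-aided Nile-red relative fluorescence
#' (RFU) replicates, optionally with gravimetric lipid titre and lipid
#' content. RFU is a proxy for neutral lipid: the screening workflow ranks
#' strains by mean RFU and validates the proxy against gravimetric values.
#'
#' @param strain_id Character vector of unique strain identifiers.
#' @param rfu List of numeric vectors (>= 1 replicate per strain, all >= 0),
#'   or a matrix with one row per strain.
#' @param lipid_titre Optional gravimetric lipid titre, g/L (`NA` allowed).
#' @param lipid_content Optional lipid content, % w/w.
#' @param reference Optional character: `"high"`/`"low"` control annotations,
#'   `NA` otherwise.
#' @return Object of class `screening_table`: data.frame with a list column
#'   `rfu`.
#' @export
screening_table <- function(strain_id, rfu, lipid_titre = NA_real_,
                            lipid_content = NA_real_, reference = NA_character_) {
  strain_id <- as.character(strain_id)
  if (anyDuplicated(strain_id)) stop("strain ids must be unique", call. = FALSE)
  if (is.matrix(rfu)) rfu <- lapply(seq_len(nrow(rfu)), function(i) rfu[i, ])
  if (!is.list(rfu) || length(rfu) != length(strain_id)) {
    stop("'rfu' must be a list of replicate vectors, one per strain",
         call. = FALSE)
  }
  rfu <- lapply(rfu, function(v) as.numeric(v[!is.na(v)]))
  if (any(vapply(rfu, length, 1L) < 1L)) {
    stop("every strain needs at least one RFU replicate", call. = FALSE)
  }
  if (any(unlist(rfu) < 0)) stop("RFU values must be >= 0", call. = FALSE)
  df <- data.frame(strain_id = strain_id,
                   lipid_titre = rep_len(as.numeric(lipid_titre),
                                         length(strain_id)),
                   lipid_content = rep_len(as.numeric(lipid_content),
                                           length(strain_id)),
                   reference = rep_len(as.character(reference),
                                       length(strain_id)),
                   stringsAsFactors = FALSE)
  df$rfu <- rfu
  structure(df, class = c("screening_table", "data.frame"))
}

#' @export
print.screening_table <- function(x, ...) {
  cat(sprintf("Screening table: %d strains, %s RFU replicates each\n",
              nrow(x),
              paste(range(vapply(x$rfu, length, 1L)), collapse = "-")))
  df <- data.frame(strain_id = x$strain_id,
                   mean_rfu = vapply(x$rfu, mean, 1.0),
                   lipid_titre = x$lipid_titre,
                   lipid_content = x$lipid_content)
  print(utils::head(df, 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Read a screening CSV
#'
#' Dialect: `strain_id,rfu_1..rfu_k,lipid_titre_g_l,lipid_content_pct`.
#' Ragged replicate columns are permitted (empty cells ignored); the two
#' lipid columns are optional.
#'
#' @param path File path.
#' @return A [screening_table()].
#' @export
read_screening_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"strain_id" %in% names(df)) {
    stop("screening CSV needs a 'strain_id' column: ", path, call. = FALSE)
  }
  rfu_cols <- grep("^rfu_[0-9]+$", names(df), value = TRUE)
  if (!length(rfu_cols)) {
    stop("screening CSV needs rfu_1..rfu_k columns: ", path, call. = FALSE)
  }
  rfu <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, rfu_cols])
    v[!is.na(v)]
  })
  screening_table(df$strain_id, rfu,
                  lipid_titre = if ("lipid_titre_g_l" %in% names(df))
                    df$lipid_titre_g_l else NA_real_,
                  lipid_content = if ("lipid_content_pct" %in% names(df))
                    df$lipid_content_pct else NA_real_)
}

#' @rdname read_screening_csv
#' @param table A [screening_table()].
#' @export
write_screening_csv <- function(table, path) {
  stopifnot(inherits(table, "screening_table"))
  k <- max(vapply(table$rfu, length, 1L))
  rfu <- t(vapply(table$rfu, function(v) {
    length(v) <- k
    v
  }, numeric(k)))
  colnames(rfu) <- paste0("rfu_", seq_len(k))
  df <- cbind(data.frame(strain_id = table$strain_id), as.data.frame(rfu),
              data.frame(lipid_titre_g_l = table$lipid_titre,
                         lipid_content_pct = table$lipid_content))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rank strains by mean Nile-red fluorescence
#'
#' Orders strains by descending mean RFU; ties are broken lexicographically
#' by strain id. Replicate dispersion is reported as the sample standard
#' deviation.
#'
#' @param table A [screening_table()].
#' @return Data.frame `strain_id`, `mean_rfu`, `sd_rfu`, `n_replicates`,
#'   `rank`.
#' @export
rank_by_rfu <- function(table) {
  stopifnot(inherits(table, "screening_table"))
  if (nrow(table) == 0) {
    return(data.frame(strain_id = character(0), mean_rfu = numeric(0),
                      sd_rfu = numeric(0), n_replicates = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  m <- vapply(table$rfu, mean, 1.0)
  s <- vapply(table$rfu, function(v) if (length(v) > 1) stats::sd(v) else 0,
              1.0)
  ord <- order(-m, table$strain_id, method = "radix")
  data.frame(strain_id = table$strain_id[ord], mean_rfu = m[ord],
             sd_rfu = s[ord],
             n_replicates = vapply(table$rfu, length, 1L)[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Classify a strain as oleaginous
#'
#' A strain is called oleaginous when its lipid content strictly exceeds the
#' threshold (default 20% of dry cell weight, the conventional cutoff for
#' single-cell-oil candidates).
#'
#' @param lipid_content Percent w/w, in `[0, 100]`.
#' @param threshold Percent cutoff, default 20.
#' @return Logical.
#' @examples
#' classify_oleaginous(54.24)  # TRUE
#' classify_oleaginous(20)     # FALSE: strict inequality
#' @export
classify_oleaginous <- function(lipid_content, threshold = 20) {
  if (any(is.na(lipid_content)) ||
      any(lipid_content < 0 | lipid_content > 100)) {
    stop("lipid content must lie in [0, 100]", call. = FALSE)
  }
  lipid_content > threshold
}

#' Correlation between Nile-red RFU and gravimetric lipid
#'
#' Pearson product-moment correlation between per-strain mean RFU and
#' gravimetric lipid titre, with the two-sided t-test p-value from
#' [stats::cor.test()]. Replicates are averaged per strain before
#' correlating (set `per_replicate = TRUE` to instead pair every replicate
#' with its strain's lipid value).
#'
#' @param table A [screening_table()] with >= 3 strains carrying both RFU
#'   and lipid titre.
#' @param per_replicate Correlate per replicate instead of per strain mean.
#' @return List with `r`, `n`, `p_value`.
#' @export
rfu_lipid_correlation <- function(table, per_replicate = FALSE) {
  stopifnot(inherits(table, "screening_table"))
  keep <- !is.na(table$lipid_titre)
  if (per_replicate) {
    x <- unlist(table$rfu[keep])
    y <- rep(table$lipid_titre[keep], vapply(table$rfu[keep], length, 1L))
  } else {
    x <- vapply(table$rfu[keep], mean, 1.0)
    y <- table$lipid_titre[keep]
  }
  if (length(x) < 3) {
    stop("need >= 3 strains with both RFU and lipid titre", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in RFU or lipid",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}
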