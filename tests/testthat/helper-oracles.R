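# Independent oracles and case generators shared across test files.

# Brute-force per-component SV/IV: explicit loop over species, recomputing
# each methyl-ester weight from atomic masses, independent of the package's
# vectorized path.
oracle_sv_iv <- function(fractions) {
  sv <- 0
  iv <- 0
  for (lab in names(fractions)) {
    parts <- as.integer(strsplit(sub("^C", "", lab), ":")[[1]])
    n <- parts[1]
    d <- parts[2]
    mw <- 12.011 * (n + 1) + 1.008 * (2 * n + 2 - 2 * d) + 31.998
    sv <- sv + 560 * fractions[[lab]] / mw
    iv <- iv + 254 * d * fractions[[lab]] / mw
  }
  c(sv = sv, iv = iv)
}

# Random valid FAME profile over a pool of common species.
random_profile <- function(n_species = 6) {
  pool <- c("C14:0", "C15:0", "C16:0", "C16:1", "C18:0", "C18:1", "C18:2",
            "C18:3", "C20:0", "C22:0", "C24:0")
  labs <- sample(pool, n_species)
  w <- stats::runif(n_species)
  fame_profile(stats::setNames(100 * w / sum(w), labs), normalized = TRUE)
}

# Fisher-z 95% band around a population correlation at sample size n.
fisher_z_band <- function(rho, n) {
  se <- 1 / sqrt(n - 3)
  tanh(atanh(rho) + c(-1.96, 1.96) * se)
}

# The as-printed AS-PSH FAME composition (weight percent).
as_psh_fractions <- c("C14:0" = 0.89, "C15:0" = 0.1, "C16:0" = 28.85,
                      "C18:1" = 52.58, "C18:2" = 12.45, "C18:3" = 1.37,
                      "C22:0" = 0.46)

extdata <- function(f) system.file("extdata", f, package = "oleofuel")
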