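## Shared fixture builders and independent oracles for the test suite.
## Everything is generated in code at test time; no stored data.

## Analysis-style table with a single variant and measure, built directly
## from the linear structural equations so every path coefficient is known.
## Returns a data.frame ready for fit_path_a()/bootstrap_acme().
make_linear_mediation_data <- function(n, a, b, c_prime, seed,
                                       freq = 0.3, residual_sd_m = 1,
                                       residual_sd_y = 1,
                                       variant = "snp1",
                                       region = "hippocampus",
                                       measure_type = "volume") {
  set.seed(seed)
  dosage <- stats::rbinom(n, 2L, freq)
  age <- stats::rnorm(n, 70, 7)
  sex <- stats::rbinom(n, 1L, 0.5)
  gcov <- stats::rnorm(n)
  m <- a * dosage + 0.02 * (age - 70) + 0.1 * sex +
    stats::rnorm(n, 0, residual_sd_m)
  y <- c_prime * dosage + b * m + 0.01 * (age - 70) +
    stats::rnorm(n, 0, residual_sd_y)
  d <- data.frame(age = age, sex = sex, outcome = y)
  d[[variant]] <- dosage
  d[[paste0(region, "__", measure_type)]] <- m
  d[[global_covariate_for(measure_type)]] <- gcov
  attr(d, "outcome_family") <- "linear"
  d
}

## Independent weighted-median oracle: brute-force interpolation on the
## cumulative standardized weights, written from the definition without
## reference to the package implementation.
oracle_weighted_median <- function(bx, by, sey) {
  ratios <- by / bx
  w <- (bx / sey)^2
  ord <- order(ratios)
  r <- ratios[ord]
  wn <- w[ord] / sum(w)
  s <- numeric(length(r))
  for (j in seq_along(r)) s[j] <- sum(wn[seq_len(j)]) - wn[j] / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(r)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  above <- below + 1L
  r[below] + (r[above] - r[below]) * (0.5 - s[below]) / (s[above] - s[below])
}

## Generic weighted-least-squares oracle through lm(); used to cross-check
## IVW (through the origin) and MR-Egger (with intercept).
oracle_wls <- function(bx, by, sey, intercept) {
  f <- if (intercept) by ~ bx else by ~ bx - 1
  stats::coef(stats::lm(f, weights = 1 / sey^2))
}

## Small full-catalog cortical tables for global_measures() checks.
make_cortical_tables <- function(n, seed = 1) {
  set.seed(seed)
  regions <- cortical_regions()
  area <- matrix(stats::runif(n * length(regions), 500, 5000), nrow = n,
                 dimnames = list(NULL, regions))
  thick <- matrix(stats::runif(n * length(regions), 1.5, 3.5), nrow = n,
                  dimnames = list(NULL, regions))
  list(area = as.data.frame(area), thickness = as.data.frame(thick))
}
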