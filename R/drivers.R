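# Synthetic driver populations: behavioural class, desired free-flow speed
# (DFFS) and telematics flag. Replaces the telematics-derived empirical
# distributions with configurable truncated normals.

#' Default DFFS distribution parameters
#'
#' Per-group truncated-normal parameters (km/h) for the desired free-flow
#' speed. Group A (law-abiding) lies at or below the 90 km/h limit; groups B
#' (kangaroo) and C (consistent speeder) lie strictly above it, C fastest.
#'
#' @return Named list with elements `A`, `B`, `C`, each a list with `mean`,
#'   `sd`, `lower`, `upper` in km/h. Truncation is to `(lower, upper]`.
#' @export
default_dffs_params <- function() {
  list(
    A = list(mean = 84,  sd = 4, lower = 0,  upper = 90),
    B = list(mean = 100, sd = 6, lower = 90, upper = 140),
    C = list(mean = 110, sd = 8, lower = 90, upper = 160)
  )
}

#' Population specification
#'
#' Describes the composition of a synthetic driver population: shares of the
#' behavioural groups, the telematics installation rate among violators
#' (groups B and C), and the per-group DFFS distributions.
#'
#' @param pct_B Percentage of group B (kangaroo) drivers, 0-100.
#' @param pct_C Percentage of group C (consistent speeder) drivers, 0-100.
#' @param pct_telematics Percentage of the B-and-C pool equipped with a
#'   telematics enforcement device, 0-100.
#' @param dffs_params Per-group DFFS distribution parameters, see
#'   [default_dffs_params()].
#' @param speed_limit Speed limit in km/h (default 90).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(pct_B, pct_C, pct_telematics = 0,
                            dffs_params = default_dffs_params(),
                            speed_limit = 90) {
  stopifnot(is.numeric(pct_B), is.numeric(pct_C), is.numeric(pct_telematics),
            length(pct_B) == 1, length(pct_C) == 1, length(pct_telematics) == 1)
  if (pct_B < 0 || pct_C < 0 || pct_telematics < 0 ||
      pct_B > 100 || pct_C > 100 || pct_telematics > 100)
    stop("percentages must lie in [0, 100]")
  if (pct_B + pct_C > 100)
    stop("pct_B + pct_C exceeds 100: no room for group A")
  if (!all(c("A", "B", "C") %in% names(dffs_params)))
    stop("dffs_params must contain entries for groups A, B and C")
  if (speed_limit <= 0) stop("speed_limit must be positive")
  structure(
    list(pct_B = pct_B, pct_C = pct_C, pct_telematics = pct_telematics,
         dffs_params = dffs_params, speed_limit = speed_limit),
    class = "population_spec")
}

# Inverse-CDF sampler for a normal truncated to (lower, upper].
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi <= plo) stop("empty truncation interval")
  x <- qnorm(runif(n, plo, phi), mean, sd)
  # guard the open lower bound against round-off at the quantile edge
  x[x <= lower] <- lower + 1e-9
  pmin(x, upper)
}

#' Sample desired free-flow speeds for one driver group
#'
#' Draws from the group's truncated-normal DFFS distribution. By
#' construction group A values never exceed the speed limit and group B/C
#' values always do.
#'
#' @param group One of `"A"`, `"B"`, `"C"`.
#' @param spec A [population_spec()].
#' @param n Number of draws.
#' @return Numeric vector of speeds in km/h.
#' @export
sample_dffs <- function(group, spec, n = 1) {
  if (!is.character(group) || length(group) != 1 ||
      !group %in% c("A", "B", "C"))
    stop("unknown driver group: ", paste(group, collapse = ", "))
  p <- spec$dffs_params[[group]]
  rtrunc_norm(n, p$mean, p$sd, p$lower, p$upper)
}

#' Sample a driver population
#'
#' Group counts are the deterministic largest-remainder rounding of the
#' nominal shares, so a scenario's composition is exact rather than
#' multinomial. Telematics devices are assigned to a uniformly random subset
#' of the B-and-C pool of size `round(pct_telematics/100 * pool size)`.
#'
#' @param spec A [population_spec()].
#' @param n Population size (>= 1).
#' @return A data frame with columns `driver_id`, `group`, `dffs_kmh`,
#'   `telematics`.
#' @export
sample_population <- function(spec, n) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  n <- as.integer(n)
  shares <- c(A = 100 - spec$pct_B - spec$pct_C,
              B = spec$pct_B, C = spec$pct_C) * n / 100
  base <- floor(shares)
  need <- n - sum(base)
  if (need > 0) {
    ord <- order(-(shares - base), seq_along(shares))  # ties broken A < B < C
    base[ord[seq_len(need)]] <- base[ord[seq_len(need)]] + 1
  }
  groups <- rep(c("A", "B", "C"), times = base)
  dffs <- numeric(n)
  for (g in c("A", "B", "C")) {
    k <- sum(groups == g)
    if (k > 0) dffs[groups == g] <- sample_dffs(g, spec, k)
  }
  # random driver order, so arrival-time cycling mixes the groups
  perm <- sample.int(n)
  groups <- groups[perm]
  dffs <- dffs[perm]
  telem <- rep(FALSE, n)
  pool <- which(groups != "A")
  k_tel <- round(spec$pct_telematics / 100 * length(pool))
  if (k_tel > 0)
    telem[pool[sample.int(length(pool), k_tel)]] <- TRUE
  data.frame(driver_id = seq_len(n), group = groups,
             dffs_kmh = dffs, telematics = telem,
             stringsAsFactors = FALSE)
}

#' Write / read a driver population as CSV
#'
#' Columns: `driver_id, group, dffs_kmh, telematics` with telematics encoded
#' as 0/1. The round trip preserves all fields.
#'
#' @param population Data frame from [sample_population()].
#' @param path File path.
#' @export
write_population <- function(population, path) {
  out <- population
  out$telematics <- as.integer(out$telematics)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("driver_id", "group", "dffs_kmh", "telematics")
  miss <- setdiff(req, names(pop))
  if (length(miss)) stop("population file missing columns: ",
                         paste(miss, collapse = ", "))
  pop$telematics <- as.logical(pop$telematics)
  pop
}
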