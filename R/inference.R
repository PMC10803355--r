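# Inference over the scenario grid: the RUD regression, implementation-cell
# classifiers, the power-model crash-risk translation, and the spill-over
# linearity check.

#' Linear regression of RUD on scenario factors
#'
#' Ordinary least squares of per-run RUD on camera-layout indicators
#' (reference: one fixed camera), demand per 1000 VPH, group shares and the
#' telematics installation rate, with classical standard errors and normal
#' 95% confidence intervals (coefficient +/- 1.96 SE).
#'
#' @param results Scenario-results table (as produced by [run_batch()]);
#'   needs `rud_pct`, `sec_type`, `demand_vph`, `pct_B`, `pct_C`,
#'   `telematics_pct`.
#' @return Object of class `rud_regression`: list with `table` (variable,
#'   coefficient, ci_low, ci_high, se, t, p), `r_squared`, `adj_r_squared`,
#'   `n` and the underlying `lm` fit.
#' @export
fit_rud_regression <- function(results) {
  req <- c("rud_pct", "sec_type", "demand_vph", "pct_B", "pct_C",
           "telematics_pct")
  miss <- setdiff(req, names(results))
  if (length(miss)) stop("results missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(results$rud_pct)) stop("missing rud_pct outcomes")
  d <- data.frame(
    rud_pct = results$rud_pct,
    sec_FIX2 = as.integer(results$sec_type == "FIX2"),
    sec_FIX3 = as.integer(results$sec_type == "FIX3"),
    sec_P2P = as.integer(results$sec_type == "P2P"),
    demand_per_1000vph = results$demand_vph / 1000,
    pct_B = results$pct_B, pct_C = results$pct_C,
    telematics_pct = results$telematics_pct)
  X <- as.matrix(cbind(intercept = 1, d[, -1]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lm(rud_pct ~ sec_FIX2 + sec_FIX3 + sec_P2P + demand_per_1000vph +
              pct_B + pct_C + telematics_pct, data = d)
  s <- summary(fit)
  co <- s$coefficients
  z <- qnorm(0.975)
  tab <- data.frame(
    variable = rownames(co),
    coefficient = co[, 1],
    ci_low = co[, 1] - z * co[, 2],
    ci_high = co[, 1] + z * co[, 2],
    se = co[, 2], t = co[, 3], p = co[, 4],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared, n = nrow(d), model = fit),
            class = "rud_regression")
}

#' @export
print.rud_regression <- function(x, ...) {
  cat("RUD regression (OLS), n =", x$n, "\n")
  cat(sprintf("R^2 = %.4f, adjusted R^2 = %.4f\n", x$r_squared,
              x$adj_r_squared))
  tab <- x$table
  tab$p <- format_pvalue(tab$p)
  print(tab, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Format p-values for reporting
#'
#' Values below 0.001 are reported as `"<0.001"`.
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
}

#' Write the regression table as CSV
#'
#' Columns `variable, coefficient, ci_low, ci_high, se, t, p` with p-values
#' below 0.001 printed as `<0.001`.
#' @param fit A `rud_regression`.
#' @param path Output path.
#' @export
write_regression_csv <- function(fit, path) {
  tab <- fit$table
  tab$p <- format_pvalue(tab$p)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Implementation-cell classifiers
#'
#' Map grid coordinates onto the implementation scenarios used for the
#' crash-risk comparison. Combinations outside the defined ranges return
#' `NA` and are excluded. On exact boundary ties the community priority is
#' law-abiding > average > law-avoiding > law-carefree, which makes the
#' classification deterministic.
#'
#' Communities: law-abiding (B 10-20%, C 1-2%), average (B 20-30%, C 3%),
#' law-avoiding (B 35-50%, C 3%), law-carefree (B 20-30%, C 4-5%).
#' Traffic: low (500-1500 VPH), moderate (2500-3500 VPH); 2000 VPH falls in
#' neither bin. Telematics: none (0-1%), enforcement (8-10%).
#'
#' @param pct_B,pct_C Group shares in percent (vectorised).
#' @return Character vector (`NA` where no range matches).
#' @export
classify_community <- function(pct_B, pct_C) {
  n <- max(length(pct_B), length(pct_C))
  pct_B <- rep_len(pct_B, n); pct_C <- rep_len(pct_C, n)
  out <- rep(NA_character_, n)
  out[pct_B >= 20 & pct_B <= 30 & pct_C >= 4 & pct_C <= 5] <- "law-carefree"
  out[pct_B >= 35 & pct_B <= 50 & pct_C == 3] <- "law-avoiding"
  out[pct_B >= 20 & pct_B <= 30 & pct_C == 3] <- "average"
  out[pct_B >= 10 & pct_B <= 20 & pct_C >= 1 & pct_C <= 2] <- "law-abiding"
  out
}

#' @rdname classify_community
#' @param demand_vph Demand in vehicles per hour.
#' @export
classify_traffic <- function(demand_vph) {
  out <- rep(NA_character_, length(demand_vph))
  out[demand_vph >= 500 & demand_vph <= 1500] <- "low"
  out[demand_vph >= 2500 & demand_vph <= 3500] <- "moderate"
  out
}

#' @rdname classify_community
#' @param pct Telematics installation percentage.
#' @export
classify_telematics <- function(pct) {
  out <- rep(NA_character_, length(pct))
  out[pct >= 0 & pct <= 1] <- "none"
  out[pct >= 8 & pct <= 10] <- "enforcement"
  out
}

#' Power-model crash relative risk
#'
#' `RR = (mean_speed_alt / mean_speed_ref)^n`; the percent change is
#' `100 * (RR - 1)`. The default exponent n = 3 corresponds to fatal and
#' serious-injury crashes.
#'
#' @param mean_speed_ref,mean_speed_alt Mean speeds (km/h) of the reference
#'   and alternative configurations; both must be positive. Vectorised.
#' @param exponent Power-model exponent n (> 0).
#' @return Data frame with `relative_risk` and `pct_change`.
#' @export
crash_relative_risk <- function(mean_speed_ref, mean_speed_alt, exponent = 3) {
  stopifnot(exponent > 0)
  if (any(mean_speed_ref <= 0) || any(mean_speed_alt <= 0))
    stop("mean speeds must be positive")
  rr <- (mean_speed_alt / mean_speed_ref)^exponent
  data.frame(relative_risk = rr, pct_change = 100 * (rr - 1))
}

#' Crash-risk comparison table across implementation cells
#'
#' Classifies every scenario-seed result into (community x traffic x
#' telematics) cells, pools distance and time per cell and camera layout
#' into one space-mean speed (totals are summed before dividing, not
#' averaged per seed), and compares each layout against the single fixed
#' camera via [crash_relative_risk()]. Cells with no classified data are
#' omitted; a populated cell lacking the FIX1 reference is an error.
#'
#' @param results Scenario-results table with `sec_type`, `pct_B`, `pct_C`,
#'   `demand_vph`, `telematics_pct`, `mean_speed_kmh`, `total_distance_vkm`
#'   (and `total_time_vh` if available).
#' @param exponent Power-model exponent.
#' @return Data frame with one row per cell and comparison: `community`,
#'   `traffic`, `telematics`, `comparison`, `mean_speed_ref`,
#'   `mean_speed_alt`, `relative_risk`, `pct_change`.
#' @export
build_crash_risk_table <- function(results, exponent = 3) {
  r <- results
  r$community <- classify_community(r$pct_B, r$pct_C)
  r$traffic <- classify_traffic(r$demand_vph)
  r$telematics <- classify_telematics(r$telematics_pct)
  r <- r[!is.na(r$community) & !is.na(r$traffic) & !is.na(r$telematics), ,
         drop = FALSE]
  if (nrow(r) == 0) return(data.frame())
  r$time_vh <- if ("total_time_vh" %in% names(r)) r$total_time_vh else
    r$total_distance_vkm / r$mean_speed_kmh
  agg <- aggregate(cbind(dist = total_distance_vkm, time = time_vh) ~
                     community + traffic + telematics + sec_type,
                   data = r, FUN = sum)
  agg$speed <- agg$dist / agg$time
  cells <- unique(agg[, c("community", "traffic", "telematics")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- agg[agg$community == cell$community & agg$traffic == cell$traffic &
                 agg$telematics == cell$telematics, , drop = FALSE]
    ref <- sub[sub$sec_type == "FIX1", , drop = FALSE]
    if (nrow(ref) == 0)
      stop("cell missing the FIX1 reference: ",
           paste(unlist(cell), collapse = " / "))
    for (alt in c("FIX2", "FIX3", "P2P")) {
      a <- sub[sub$sec_type == alt, , drop = FALSE]
      if (nrow(a) == 0) next
      rr <- crash_relative_risk(ref$speed, a$speed, exponent)
      rows[[length(rows) + 1L]] <- data.frame(
        community = cell$community, traffic = cell$traffic,
        telematics = cell$telematics,
        comparison = paste0(alt, "-vs-FIX1"),
        mean_speed_ref = ref$speed, mean_speed_alt = a$speed,
        relative_risk = rr$relative_risk, pct_change = rr$pct_change,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spill-over linearity of RUD in the telematics rate
#'
#' For each (camera layout x demand) combination, fits a least-squares line
#' of mean RUD against the telematics installation percentage and reports
#' slope, R-squared and the largest absolute residual. A relatively linear
#' trend (high R-squared) indicates the absence of a spill-over effect at
#' high installation rates.
#'
#' @param results Spill-over grid results with `sec_type`, `demand_vph`,
#'   `telematics_pct`, `rud_pct`.
#' @return Data frame with `sec_type`, `demand_vph`, `slope`, `intercept`,
#'   `r_squared`, `max_abs_residual`, `n_levels`.
#' @export
spillover_linearity <- function(results) {
  agg <- aggregate(rud_pct ~ sec_type + demand_vph + telematics_pct,
                   data = results, FUN = mean)
  combos <- unique(agg[, c("sec_type", "demand_vph")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- agg[agg$sec_type == combos$sec_type[i] &
                 agg$demand_vph == combos$demand_vph[i], , drop = FALSE]
    if (nrow(sub) < 3)
      stop("need at least 3 telematics levels per (sec_type, demand)")
    fit <- lm(rud_pct ~ telematics_pct, data = sub)
    res <- residuals(fit)
    ssr <- sum(res^2)
    sst <- sum((sub$rud_pct - mean(sub$rud_pct))^2)
    r2 <- if (ssr < 1e-12) 1 else 1 - ssr / sst
    rows[[i]] <- data.frame(
      sec_type = combos$sec_type[i], demand_vph = combos$demand_vph[i],
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = r2, max_abs_residual = max(abs(res)),
      n_levels = nrow(sub), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
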