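# Scenario grids: the full factorial design, seed expansion, the spill-over
# grid, and reproducible (resumable) batch execution.

#' Scenario specification
#'
#' One cell of the simulation grid plus a seed: camera layout, telematics
#' installation rate among violators, group shares, and traffic demand.
#'
#' @param sec_type One of `"FIX1"`, `"FIX2"`, `"FIX3"`, `"P2P"`.
#' @param telematics_pct Telematics installation percentage among B/C, 0-100.
#' @param pct_B,pct_C Group shares in percent.
#' @param demand_vph Traffic demand in vehicles per hour (all lanes).
#' @param seed Integer RNG seed driving every random element of the run.
#' @export
scenario_spec <- function(sec_type, telematics_pct, pct_B, pct_C, demand_vph,
                          seed = 1L) {
  if (!sec_type %in% c("FIX1", "FIX2", "FIX3", "P2P"))
    stop("unknown sec_type: ", sec_type)
  stopifnot(telematics_pct >= 0, telematics_pct <= 100,
            pct_B >= 0, pct_C >= 0, pct_B + pct_C <= 100, demand_vph >= 0)
  structure(list(sec_type = sec_type, telematics_pct = telematics_pct,
                 pct_B = pct_B, pct_C = pct_C, demand_vph = demand_vph,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param scenario A scenario (list or `scenario_spec`).
#' @return `scenario_id()`: a deterministic identifier string for the grid
#'   cell (seed excluded).
#' @export
scenario_id <- function(scenario) {
  sprintf("%s_t%g_B%g_C%g_d%g", scenario$sec_type, scenario$telematics_pct,
          scenario$pct_B, scenario$pct_C, scenario$demand_vph)
}

#' The full factorial grid of the study design
#'
#' Four camera layouts, telematics 0-10% in steps of 1, group B 10-50% in
#' steps of 5, group C 1-5% in steps of 1, and demand 500-3500 VPH in steps
#' of 500: 4 x 11 x 9 x 5 x 7 = 13,860 scenarios.
#'
#' @return Named list of factor levels.
#' @export
default_grid <- function() {
  list(sec_type = c("FIX1", "FIX2", "FIX3", "P2P"),
       telematics_pct = 0:10,
       pct_B = seq(10, 50, by = 5),
       pct_C = 1:5,
       demand_vph = seq(500, 3500, by = 500))
}

#' Enumerate the scenario grid
#'
#' Full Cartesian product of the factor levels in deterministic
#' lexicographic order (`sec_type` slowest, `demand_vph` fastest).
#'
#' @param grid Named list of factor levels, as [default_grid()].
#' @return Data frame of scenarios without seeds.
#' @export
enumerate_scenarios <- function(grid = default_grid()) {
  req <- c("sec_type", "telematics_pct", "pct_B", "pct_C", "demand_vph")
  miss <- setdiff(req, names(grid))
  if (length(miss)) stop("grid missing factors: ", paste(miss, collapse = ", "))
  if (any(vapply(grid[req], length, 1L) == 0))
    stop("empty factor in grid")
  g <- expand.grid(demand_vph = grid$demand_vph, pct_C = grid$pct_C,
                   pct_B = grid$pct_B, telematics_pct = grid$telematics_pct,
                   sec_type = grid$sec_type,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(names(g))]
  rownames(g) <- NULL
  g
}

#' Replicate scenarios across seeds
#'
#' Each scenario is replicated with `n_seeds` distinct seeds derived
#' counter-based from `master_seed`. The seed list is shared by all
#' scenarios (common random numbers), so for a given seed the driver
#' population and arrival process are identical across camera layouts and
#' layout contrasts are paired comparisons; adding scenarios never perturbs
#' existing seeds.
#'
#' @param scenarios Data frame from [enumerate_scenarios()].
#' @param n_seeds Number of replicate seeds per scenario (default 30).
#' @param master_seed Integer from which the seed list is derived.
#' @return Data frame with one row per (scenario, seed).
#' @export
expand_seeds <- function(scenarios, n_seeds = 30, master_seed = 1) {
  stopifnot(n_seeds >= 1)
  seeds <- ((as.integer(master_seed) - 1L + seq_len(n_seeds) - 1L) %%
              2147483646L) + 1L
  out <- scenarios[rep(seq_len(nrow(scenarios)), each = n_seeds), ,
                   drop = FALSE]
  out$seed <- rep(seeds, times = nrow(scenarios))
  rownames(out) <- NULL
  out
}

#' The spill-over grid
#'
#' High telematics installation rates (10-90% in steps of 10) at the average
#' community composition (30% B, 3% C) for demands above 1500 VPH, across
#' all four camera layouts: 9 x 4 x 4 = 144 scenarios.
#'
#' @return Data frame of scenarios without seeds.
#' @export
enumerate_spillover_grid <- function() {
  enumerate_scenarios(list(sec_type = c("FIX1", "FIX2", "FIX3", "P2P"),
                           telematics_pct = seq(10, 90, by = 10),
                           pct_B = 30, pct_C = 3,
                           demand_vph = c(2000, 2500, 3000, 3500)))
}

#' Run a batch of scenario-seed specs
#'
#' Executes [run_simulation()] plus [scenario_results()] for every row.
#' When `output_csv` is given, rows are appended as they complete and a
#' rerun skips (scenario_id, seed) pairs already present, so an interrupted
#' batch resumes to the same final table. Per-spec failures are collected
#' and reported at the end; an error is raised if any spec failed.
#'
#' @param specs Data frame with scenario columns plus `seed` (from
#'   [expand_seeds()]).
#' @param road A [road_spec()].
#' @param params A [sim_params()].
#' @param output_csv Optional path of the results CSV (enables resuming).
#' @param progress Print a heartbeat every `progress` completed specs
#'   (0 = silent).
#' @param dffs_params Per-group DFFS distribution parameters.
#' @return Results data frame, one row per spec (including previously
#'   completed rows when resuming).
#' @export
run_batch <- function(specs, road = road_spec(), params = sim_params(),
                      output_csv = NULL, progress = 0,
                      dffs_params = default_dffs_params()) {
  stopifnot(nrow(specs) >= 1, "seed" %in% names(specs))
  prior <- NULL
  done <- character(0)
  if (!is.null(output_csv) && file.exists(output_csv)) {
    prior <- read.csv(output_csv, stringsAsFactors = FALSE)
    done <- paste(prior$scenario_id, prior$seed)
  }
  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- as.list(specs[i, ])
    key <- paste(scenario_id(sp), sp$seed)
    if (key %in% done) next
    res <- tryCatch({
      sim <- run_simulation(sp, road = road, params = params, record = FALSE,
                            dffs_params = dffs_params)
      scenario_results(sim)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      next
    }
    rows[[key]] <- res
    if (!is.null(output_csv)) {
      write.table(res, output_csv, sep = ",", append = file.exists(output_csv),
                  col.names = !file.exists(output_csv), row.names = FALSE,
                  qmethod = "double")
    }
    if (progress > 0 && length(rows) %% progress == 0)
      message(sprintf("[run_batch] %d/%d specs done", length(rows) +
                        length(done), nrow(specs)))
  }
  if (length(failures))
    stop("run_batch: ", length(failures), " spec(s) failed:\n",
         paste(names(failures), unlist(failures), sep = ": ",
               collapse = "\n"))
  out <- do.call(rbind, c(list(prior), unname(rows)))
  rownames(out) <- NULL
  out
}
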