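# Experiments: replicate batches, parameter sweeps, the MRR statistic with
# bootstrap intervals, regression fits, and baseline (n, m) calibration.

#' Run a batch of replicate simulations
#'
#' The network, leader set and control assignment are fixed across
#' replicates; replicate `i` runs with the seed `derive_seed(base_seed,
#' cell, i)` so any single replicate is reproducible in isolation.
#'
#' @param net a `social_network`.
#' @param cfg a [sim_config()].
#' @param leaders leader node ids.
#' @param controls optional [control_assignment()]; by default placed from
#'   `cfg$saints` / `cfg$devils` / `cfg$placement` with a seed derived from
#'   `base_seed`.
#' @param replicates number of replicate runs (>= 1).
#' @param base_seed integer seed for the whole batch.
#' @param cell sweep cell index mixed into replicate seeds (0 for a lone
#'   batch).
#' @param n_boot bootstrap resamples for the percentile 95% CI of the mean
#'   MRR (0 disables).
#' @return a `batch_result`: `replicate_mrrs`, `mean_mrr`, `se_mrr`, `ci95`,
#'   `mean_generations`, `median_generations`, `fraction_converged`,
#'   `replicates` data frame, `config`, `controls`.
#' @export
run_batch <- function(net, cfg, leaders, controls = NULL, replicates = 100L,
                      base_seed = 1L, cell = 0L, n_boot = 1000L) {
  if (!is_count(replicates, 1L)) rn_param_error("replicates must be >= 1")
  if (is.null(controls)) {
    controls <- place_controls(
      net, role = "saint", count = cfg$saints, mode = cfg$placement,
      leaders = leaders, seed = derive_seed(base_seed, cell, 777001L))
    if (cfg$devils > 0L) {
      dev <- place_controls(
        net, role = "devil", count = cfg$devils, mode = cfg$placement,
        leaders = c(leaders, controls$saints),
        seed = derive_seed(base_seed, cell, 777002L))
      controls <- control_assignment(saints = controls$saints,
                                     devils = dev$devils,
                                     placement_mode = cfg$placement)
    }
  }
  seeds <- vapply(seq_len(replicates) - 1L,
                  function(i) derive_seed(base_seed, cell, i), integer(1))
  mrr <- numeric(replicates); gens <- integer(replicates); conv <- logical(replicates)
  for (i in seq_len(replicates)) {
    run <- run_simulation(net, cfg, leaders, controls, seed = seeds[i])
    mrr[i] <- run$mrr; gens[i] <- run$generations; conv[i] <- run$converged
  }
  ci <- if (n_boot > 0L && replicates > 1L) {
    boot_ci_mean(mrr, n_boot, derive_seed(base_seed, cell, 888001L))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(
    replicate_mrrs = mrr,
    mean_mrr = mean(mrr),
    se_mrr = if (replicates > 1L) stats::sd(mrr) / sqrt(replicates) else NA_real_,
    ci95 = ci,
    mean_generations = mean(gens),
    median_generations = stats::median(gens),
    fraction_converged = mean(conv),
    replicates = data.frame(replicate = seq_len(replicates) - 1L, seed = seeds,
                            mrr = mrr, generations = gens, converged = conv),
    config = cfg,
    controls = controls,
    base_seed = as.integer(base_seed),
    cell = as.integer(cell)
  ), class = "batch_result")
}

# Percentile bootstrap CI for the mean.
boot_ci_mean <- function(x, n_boot, seed) {
  withr::with_seed(as.integer(seed), {
    n <- length(x)
    means <- vapply(seq_len(n_boot),
                    function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    unname(stats::quantile(means, c(0.025, 0.975)))
  })
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf(
    "<batch_result> %d replicates: mean MRR %.3f [%.3f, %.3f], median %d generations, %.0f%% converged\n",
    nrow(x$replicates), x$mean_mrr, x$ci95[1L], x$ci95[2L],
    as.integer(x$median_generations), 100 * x$fraction_converged))
  invisible(x)
}

#' Sweep one parameter across a set of values
#'
#' Runs one batch per value. The network and leader set are shared across
#' all cells; replicate seeds are derived from `(base_seed, cell index,
#' replicate index)`. For control-count sweeps (`saint_count`,
#' `devil_count`) an ordinary least-squares regression of mean MRR on the
#' count is attached.
#'
#' @param net a `social_network`.
#' @param cfg the base [sim_config()].
#' @param leaders leader node ids.
#' @param parameter one of `"r"`, `"alpha"`, `"saint_count"`,
#'   `"devil_count"`, `"placement"`.
#' @param values vector of parameter values, each valid for the parameter.
#' @param replicates replicates per cell.
#' @param base_seed integer seed for the sweep.
#' @param n_boot bootstrap resamples per cell.
#' @return a `sweep_result`: `parameter`, `values`, `batches` (list of
#'   [run_batch()] results), `summary` data frame, and optional `regression`.
#' @export
param_sweep <- function(net, cfg, leaders, parameter, values, replicates = 100L,
                  base_seed = 1L, n_boot = 1000L) {
  parameter <- match.arg(parameter,
                         c("r", "alpha", "saint_count", "devil_count", "placement"))
  if (length(values) == 0L) rn_config_error("values must be nonempty")
  batches <- vector("list", length(values))
  for (j in seq_along(values)) {
    v <- values[[j]]
    cfg_j <- cfg
    cfg_j[[switch(parameter,
                  r = "r", alpha = "alpha",
                  saint_count = "saints", devil_count = "devils",
                  placement = "placement")]] <-
      if (parameter %in% c("saint_count", "devil_count")) {
        if (!is_count(v)) rn_config_error("control counts must be nonnegative integers")
        as.integer(v)
      } else if (parameter == "placement") {
        if (!v %in% c("random", "top_degree")) {
          rn_config_error(sprintf("invalid placement '%s'", v))
        }
        v
      } else if (parameter == "alpha") {
        if (!is.numeric(v) || v <= 0 || v > 1) rn_config_error("alpha values must lie in (0, 1]")
        v
      } else {
        if (!(is_count(v, 1L) || identical(v, Inf))) rn_config_error("r values must be integers >= 1 or Inf")
        v
      }
    batches[[j]] <- run_batch(net, cfg_j, leaders, controls = NULL,
                              replicates = replicates, base_seed = base_seed,
                              cell = j, n_boot = n_boot)
  }
  mean_mrrs <- vapply(batches, function(b) b$mean_mrr, numeric(1))
  summary_df <- data.frame(
    value = if (parameter == "placement") as.character(values) else as.numeric(values),
    mean_mrr = mean_mrrs,
    se_mrr = vapply(batches, function(b) b$se_mrr, numeric(1)),
    ci_lo = vapply(batches, function(b) b$ci95[1L], numeric(1)),
    ci_hi = vapply(batches, function(b) b$ci95[2L], numeric(1)),
    mean_generations = vapply(batches, function(b) b$mean_generations, numeric(1)),
    fraction_converged = vapply(batches, function(b) b$fraction_converged, numeric(1))
  )
  regression <- NULL
  if (parameter %in% c("saint_count", "devil_count") && length(values) >= 3L) {
    regression <- fit_mrr_regression(as.numeric(values), mean_mrrs)
  }
  structure(list(parameter = parameter, values = values, batches = batches,
                 summary = summary_df, regression = regression,
                 base_seed = as.integer(base_seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> over %s:\n", x$parameter))
  print(x$summary[, c("value", "mean_mrr", "ci_lo", "ci_hi")], row.names = FALSE)
  if (!is.null(x$regression)) {
    cat(sprintf("  OLS: slope %.4g, intercept %.4g, R^2 %.3f\n",
                x$regression$slope, x$regression$intercept, x$regression$r_squared))
  }
  invisible(x)
}

#' Ordinary least-squares fit of mean MRR on control count
#'
#' Fit on batch means (one point per count), matching how intervention
#' dose-response curves are summarised. A constant response is reported as
#' slope 0 with `r_squared` 0.
#'
#' @param counts numeric vector of control counts (>= 3 points).
#' @param mean_mrrs mean MRR per count.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fit_mrr_regression <- function(counts, mean_mrrs) {
  if (length(counts) < 3L || length(counts) != length(mean_mrrs)) {
    rn_param_error("need >= 3 (count, mean MRR) points")
  }
  if (stats::var(mean_mrrs) == 0) {
    return(list(slope = 0, intercept = mean_mrrs[1L], r_squared = 0))
  }
  fit <- stats::lm(mean_mrrs ~ counts)
  # R^2 by hand: summary.lm() warns on exact fits
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((mean_mrrs - mean(mean_mrrs))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Calibrate the nucleus size and raid threshold against a neutral baseline
#'
#' Searches a grid of `(n, m)` candidates for the pair whose baseline mean
#' MRR (radius 1, `alpha = 1`, no controls) is closest to 1, so that the
#' population starts equally likely to become more or less risk-taking. Ties
#' are broken by smaller `|n - m|`, then smaller `n`, then smaller `m`.
#'
#' Because single-run MRRs are strongly bimodal (runs are absorbed near the
#' all-high or all-low state), cell means are noisy; an optional second
#' stage re-estimates the most promising cells with more replicates before
#' the final selection, which makes the chosen pair much less sensitive to
#' screening noise at a fixed simulation budget.
#'
#' @param net a `social_network`.
#' @param leaders leader node ids.
#' @param candidate_n,candidate_m candidate grids.
#' @param replicates replicates per grid cell in the screening pass.
#' @param base_seed integer seed.
#' @param cfg optional base [sim_config()] supplying the non-calibrated
#'   parameters.
#' @param refine_top re-estimate this many leading cells in a second stage
#'   (0 disables refinement).
#' @param refine_replicates replicates per refined cell.
#' @return list with the chosen `n`, `m`, the screening `grid` data frame,
#'   and (when refined) the `refined` data frame.
#' @export
calibrate_baseline <- function(net, leaders, candidate_n = 2:8,
                               candidate_m = 2:16, replicates = 60L,
                               base_seed = 1L, cfg = NULL,
                               refine_top = 0L, refine_replicates = 400L) {
  if (length(candidate_n) == 0L || length(candidate_m) == 0L) {
    rn_param_error("candidate grids must be nonempty")
  }
  cell_cfg <- function(n, m) sim_config(
    n = n, m = m, r = 1L, alpha = 1,
    reward = cfg$reward %||% 1, cost = cfg$cost %||% 1,
    max_generations = cfg$max_generations %||% 5000L,
    stall_window = cfg$stall_window %||% 100L)
  cell_mean <- function(n, m, reps, cell) {
    run_batch(net, cell_cfg(n, m), leaders, controls = control_assignment(),
              replicates = reps, base_seed = base_seed,
              cell = cell, n_boot = 0L)$mean_mrr
  }
  grid <- expand.grid(n = as.integer(candidate_n), m = as.integer(candidate_m))
  grid$mean_mrr <- vapply(seq_len(nrow(grid)), function(i) {
    cell_mean(grid$n[i], grid$m[i], replicates, i)
  }, numeric(1))

  refined <- NULL
  if (refine_top > 0L && nrow(grid) > 1L) {
    keep <- order(abs(grid$mean_mrr - 1))[seq_len(min(refine_top, nrow(grid)))]
    refined <- grid[keep, c("n", "m")]
    refined$mean_mrr <- vapply(seq_along(keep), function(j) {
      cell_mean(refined$n[j], refined$m[j], refine_replicates,
                100000L + keep[j])   # fresh seed stream per refined cell
    }, numeric(1))
    best <- select_calibration_cell(refined)
  } else {
    best <- select_calibration_cell(grid)
  }
  list(n = best$n, m = best$m,
       grid = grid[order(grid$n, grid$m), c("n", "m", "mean_mrr")],
       refined = refined)
}

# Selection rule: mean MRR closest to 1, ties by smaller |n - m|, then
# smaller n, then smaller m.
select_calibration_cell <- function(grid) {
  ord <- order(abs(grid$mean_mrr - 1), abs(grid$n - grid$m), grid$n, grid$m)
  grid[ord[1L], ]
}

#' Export batch / sweep results as tidy CSV and JSON summaries
#'
#' `batch_csv()` writes one row per replicate; `sweep_csv()` prepends the
#' swept parameter value; `sweep_json()` writes per-cell means, intervals
#' and any regression fit.
#'
#' @param x a `batch_result` or `sweep_result`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
batch_csv <- function(x, path) {
  utils::write.csv(x$replicates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname batch_csv
#' @export
sweep_csv <- function(x, path) {
  rows <- do.call(rbind, lapply(seq_along(x$batches), function(j) {
    df <- x$batches[[j]]$replicates
    cbind(data.frame(parameter = x$parameter,
                     value = rep(x$summary$value[j], nrow(df))), df)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname batch_csv
#' @export
sweep_json <- function(x, path) {
  jsonlite::write_json(
    list(parameter = x$parameter, summary = x$summary,
         regression = x$regression),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
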