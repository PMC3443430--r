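#' Scan configuration
#'
#' Parameters of the enforced-objective-flux scan.  Defaults follow the
#' published procedure: at least ten enforcement steps, flux variability
#' evaluated at 95 % of each step's optimal growth, carbon uptake fixed at
#' 10 mmol/gDCW/h, flux-scale constant `delta = 0.3`, global bounds
#' +-1000 mmol/gDCW/h.
#'
#' @param target target product reaction id.
#' @param n_steps number of scan levels (>= 10 unless `allow_small_n`).
#' @param growth_fraction fraction of the optimal growth rate fixed during
#'   the variability sweep (0 < fraction <= 1).
#' @param uptake_rate carbon-source uptake rate, mmol/gDCW/h.
#' @param delta flux-scale coupling constant.
#' @param growth_at_least if `TRUE`, the growth constraint is the relaxation
#'   `v_biomass >= fraction * Z_opt` instead of the printed equality.
#' @param allow_small_n permit `n_steps < 10` (for quick exploration only).
#' @return A `scan_config` object.
#' @export
scan_config <- function(target, n_steps = 10, growth_fraction = 0.95,
                        uptake_rate = 10, delta = 0.3,
                        growth_at_least = FALSE, allow_small_n = FALSE) {
  if (n_steps < 10 && !allow_small_n)
    stop("n_steps must be >= 10 (use allow_small_n to override)")
  stopifnot(growth_fraction > 0, growth_fraction <= 1, uptake_rate > 0)
  structure(list(target = target, n_steps = as.integer(n_steps),
                 growth_fraction = growth_fraction, uptake_rate = uptake_rate,
                 delta = delta, growth_at_least = growth_at_least),
            class = "scan_config")
}

#' Build the enforced-flux schedule
#'
#' Levels `v_enforced(k) = v_initial + (k/n) * (v_max - v_initial)` for
#' `k = 0, 1, ..., n-1`: the scan starts at the initial (minimal) product
#' flux and rises to a value adjacent to, but below, the theoretical maximum.
#' The `k = 0` baseline is included so the slope regression is anchored at
#' the unenforced state.
#'
#' @param v_initial minimal product flux.
#' @param v_max theoretical maximal product flux.
#' @param n number of levels.
#' @return A `scan_schedule`: list with `v_initial`, `v_max`, `levels`.
#' @export
make_schedule <- function(v_initial, v_max, n) {
  if (v_max < v_initial) stop("v_max is below v_initial")
  if (abs(v_max - v_initial) < 1e-12)
    warning("degenerate scan: v_initial equals v_max")
  levels <- v_initial + (seq_len(n) - 1) / n * (v_max - v_initial)
  structure(list(v_initial = v_initial, v_max = v_max, levels = levels),
            class = "scan_schedule")
}

#' Run the FVSEOF scan
#'
#' The three-step procedure, all under GR constraints and with the carbon
#' uptake fixed: (1) the minimal and theoretical maximal product fluxes give
#' the schedule; (2) at each enforced product-flux level the growth rate is
#' maximised; (3) with growth fixed at `growth_fraction` of that optimum,
#' every intracellular (non-exchange) reaction's flux is minimised and
#' maximised.  An infeasible step (possible adjacent to the theoretical
#' maximum) truncates the scan at the last feasible level with a warning.
#'
#' @param model a [metabolic_model()].
#' @param gr a [gr_constraint_set()] (or `NULL` for plain enforced-flux
#'   scanning, the ablation mode).
#' @param config a [scan_config()].
#' @return An `fvseof_scan` object: list with `config`, `schedule`, `steps`
#'   (per level: `k`, `v_enforced`, `z_opt`, `ranges` data.frame) and
#'   `truncated`.
#' @export
run_scan <- function(model, gr, config) {
  stopifnot(inherits(config, "scan_config"))
  validate_model(model)
  if (is.na(model$uptake_id)) stop("model has no carbon uptake reaction set")
  if (is.na(model$biomass_id)) stop("model has no biomass reaction set")
  extremes <- product_flux_extremes(model, config$target, gr,
                                    uptake_rate = config$uptake_rate)
  schedule <- make_schedule(extremes[["v_initial"]], extremes[["v_max"]],
                            config$n_steps)
  sweep_ids <- model$reactions$id[!model$reactions$exchange]
  steps <- list()
  truncated <- FALSE
  for (k in seq_along(schedule$levels)) {
    v_enf <- schedule$levels[k]
    fix <- stats::setNames(c(config$uptake_rate, v_enf),
                           c(model$uptake_id, config$target))
    growth <- solve_fba(model, model$biomass_id, "max", gr,
                        flux_constraints(fixed = fix))
    if (growth$status != "optimal") {
      warning("scan truncated at step k=", k - 1, ": growth maximisation ",
              growth$status, " at enforced flux ", signif(v_enf, 6))
      truncated <- TRUE
      break
    }
    z_opt <- growth$objective_value
    v_bio <- config$growth_fraction * z_opt
    extra <- if (config$growth_at_least)
      flux_constraints(fixed = fix,
                       lower = stats::setNames(v_bio, model$biomass_id))
    else
      flux_constraints(fixed = c(fix, stats::setNames(v_bio, model$biomass_id)))
    ranges <- fva(model, sweep_ids, gr, extra)
    if (any(ranges$status_min != "optimal" | ranges$status_max != "optimal")) {
      warning("scan truncated at step k=", k - 1,
              ": variability sweep infeasible at enforced flux ",
              signif(v_enf, 6))
      truncated <- TRUE
      break
    }
    steps[[k]] <- list(k = k - 1L, v_enforced = v_enf, z_opt = z_opt,
                       ranges = ranges)
  }
  if (length(steps) == 0) stop("scan infeasible at every level")
  structure(list(config = config, schedule = schedule, steps = steps,
                 truncated = truncated),
            class = "fvseof_scan")
}

#' @export
print.fvseof_scan <- function(x, ...) {
  cat("fvseof_scan:", length(x$steps), "step(s), target", x$config$target,
      if (x$truncated) "(truncated)" else "", "\n")
  invisible(x)
}

#' Long-format view of a scan
#'
#' @param x an `fvseof_scan`.
#' @param ... unused.
#' @return data.frame with columns `reaction_id`, `k`, `v_enforced`,
#'   `z_opt`, `v_min`, `v_max` (the raw material for targeting and export).
#' @export
as.data.frame.fvseof_scan <- function(x, ...) {
  do.call(rbind, lapply(x$steps, function(st)
    data.frame(reaction_id = st$ranges$reaction_id, k = st$k,
               v_enforced = st$v_enforced, z_opt = st$z_opt,
               v_min = st$ranges$v_min, v_max = st$ranges$v_max)))
}

#' Write the scan as long-format TSV
#'
#' @param scan an `fvseof_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
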