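## Targeting criteria: flux bias V_avg = (V'max + V'min)/2, flux capacity
## l_sol = V'max - V'min, and the regression slope q_slope of V_avg against
## the enforced product flux.  Candidates are classified into nine pattern
## types by the signs of the V_avg and l_sol trends, positive types are split
## into strong/weak, and ranking prefers small flux capacity (such reactions
## are most likely to realise the predicted flux).

#' Flux bias and flux capacity of per-step flux ranges
#'
#' @param v_max,v_min numeric vectors of per-step maximal and minimal fluxes.
#' @return list with `v_avg = (v_max + v_min)/2` and
#'   `l_sol = v_max - v_min`, exact arithmetic.
#' @export
compute_vavg_lsol <- function(v_max, v_min) {
  list(v_avg = (v_max + v_min) / 2, l_sol = v_max - v_min)
}

#' Per-reaction flux-variability series of a scan
#'
#' @param scan an `fvseof_scan`.
#' @return data.frame with one row per (reaction, step): `reaction_id`, `k`,
#'   `v_enforced`, `v_min`, `v_max`, `v_avg`, `l_sol`.
#' @export
variability_records <- function(scan) {
  df <- as.data.frame(scan)
  vl <- compute_vavg_lsol(df$v_max, df$v_min)
  df$v_avg <- vl$v_avg
  df$l_sol <- vl$l_sol
  df[, c("reaction_id", "k", "v_enforced", "v_min", "v_max", "v_avg", "l_sol")]
}

.ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx < .Machine$double.eps) return(NA_real_)
  sum((x - mx) * (y - my)) / sxx
}

#' Regression slope of the flux bias against the enforced product flux
#'
#' Ordinary least-squares slope of `V_avg(k)` on `v_enforced(k)`.  A positive
#' slope marks a candidate whose flux rises with enforced production.
#'
#' @param v_avg per-step flux bias values.
#' @param v_enforced per-step enforced product-flux levels.
#' @return the OLS slope; `NA` with a warning for a degenerate schedule
#'   (all levels equal).
#' @export
compute_qslope <- function(v_avg, v_enforced) {
  stopifnot(length(v_avg) == length(v_enforced), length(v_avg) >= 2)
  s <- .ols_slope(v_enforced, v_avg)
  if (is.na(s)) warning("degenerate schedule: q_slope undefined")
  s
}

#' Classify a reaction's flux pattern into one of nine types
#'
#' The OLS slopes of `V_avg` and `l_sol` against the enforced flux are each
#' trichotomised as positive (> eps), negative (< -eps) or flat.  Types 1-3
#' have rising flux bias (amplification candidates), 4-6 falling, 7-9 flat or
#' non-monotone (oscillatory profiles land here); within each triple the
#' flux-capacity trend negative/flat/positive orders the sub-type.
#'
#' @param v_avg,l_sol per-step series.
#' @param v_enforced enforced flux levels.
#' @param eps flat-band tolerance; see [evaluate_targets()] for the default.
#' @return integer pattern type in 1..9.
#' @export
classify_pattern <- function(v_avg, l_sol, v_enforced, eps = 1e-6) {
  tri <- function(s) if (is.na(s) || abs(s) <= eps) 0L else if (s > 0) 1L else -1L
  sa <- tri(.ols_slope(v_enforced, v_avg))
  sl <- tri(.ols_slope(v_enforced, l_sol))
  base <- if (sa > 0) 0L else if (sa < 0) 3L else 6L
  base + c(`-1` = 1L, `0` = 2L, `1` = 3L)[as.character(sl)][[1]]
}

#' Partition a positively correlated candidate into strong or weak
#'
#' Strong: flux bias non-decreasing at every consecutive step pair and a
#' positive overall slope.  Weak: positive overall slope with at least one
#' locally decreasing step (a partially negative local slope).
#'
#' @inheritParams classify_pattern
#' @return `"strong"`, `"weak"`, or `"none"` when the overall slope is not
#'   positive (precondition failure).
#' @export
partition_strength <- function(v_avg, v_enforced, eps = 1e-6) {
  q <- .ols_slope(v_enforced, v_avg)
  if (is.na(q) || q <= eps) return("none")
  dips <- diff(v_avg) < -eps
  if (any(dips)) "weak" else "strong"
}

#' Evaluate amplification candidates from a scan
#'
#' Computes, per swept reaction, the flux-bias/flux-capacity series, the
#' q_slope, the nine-type classification, the strong/weak partition, and a
#' flux direction.  A reaction that only ever carries negative flux and whose
#' bias becomes more negative with enforced production is an amplification
#' candidate of the reverse direction: its series is sign-flipped and it is
#' reported with `direction = "reverse"`.
#'
#' @param scan an `fvseof_scan`.
#' @param model the scanned [metabolic_model()] (for gene annotations).
#' @param eps flat-band tolerance; default `1e-6 * uptake_rate`, which makes
#'   the classification invariant under uniform flux rescaling.
#' @return data.frame with one row per reaction: `reaction_id`, `genes`,
#'   `type`, `strength`, `direction`, `q_slope`, `mean_v_avg`, `mean_l_sol`.
#' @export
evaluate_targets <- function(scan, model, eps = NULL) {
  if (is.null(eps)) eps <- 1e-6 * scan$config$uptake_rate
  rec <- variability_records(scan)
  rows <- lapply(split(rec, rec$reaction_id), function(r) {
    r <- r[order(r$k), , drop = FALSE]
    v_avg <- r$v_avg; l_sol <- r$l_sol; venf <- r$v_enforced
    direction <- "forward"
    if (all(r$v_max <= eps) && .ols_slope(venf, v_avg) < -eps) {
      v_avg <- -v_avg          # reverse-direction carrier
      direction <- "reverse"
    }
    type <- classify_pattern(v_avg, l_sol, venf, eps)
    strength <- if (type <= 3) partition_strength(v_avg, venf, eps) else "n/a"
    q <- .ols_slope(venf, v_avg)
    genes <- model$reactions$genes[match(r$reaction_id[1], model$reactions$id)]
    data.frame(reaction_id = r$reaction_id[1],
               genes = if (is.na(genes)) "" else genes,
               type = type, strength = strength, direction = direction,
               q_slope = if (is.na(q)) NA_real_ else q,
               mean_v_avg = mean(v_avg), mean_l_sol = mean(l_sol))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank amplification candidates
#'
#' Keeps the positively correlated types (1-3), excludes the biomass and
#' target reactions themselves, and sorts by strength (strong before weak),
#' then ascending mean flux capacity (small `l_sol` means the predicted flux
#' is most likely realised), then descending q_slope, then reaction id.
#'
#' @param candidates data.frame from [evaluate_targets()].
#' @param exclude reaction ids to drop (typically biomass and target).
#' @return The qualifying rows with a `rank` column, in rank order.
#' @export
rank_targets <- function(candidates, exclude = character(0)) {
  keep <- candidates$type %in% 1:3 &
    !candidates$reaction_id %in% exclude &
    candidates$strength %in% c("strong", "weak")
  df <- candidates[keep, , drop = FALSE]
  if (nrow(df) == 0) {
    df$rank <- integer(0)
    return(df)
  }
  ord <- order(match(df$strength, c("strong", "weak")), df$mean_l_sol,
               -df$q_slope, df$reaction_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Full target-identification pipeline
#'
#' Builds the GR constraints from the group file, runs the FVSEOF scan, and
#' classifies and ranks the amplification candidates.
#'
#' @param model a [metabolic_model()].
#' @param groups a [reaction_groups()] object.
#' @param config a [scan_config()].
#' @param carbon_source carbon-source metabolite id for the flux-converging
#'   index.
#' @param cofactors cofactor id list.
#' @param use_gr set `FALSE` for the plain enforced-flux ablation mode.
#' @param scope optional reaction scope for the GR constraints.
#' @return list with `gr`, `scan`, `candidates`, `ranked`.
#' @export
identify_targets <- function(model, groups, config, carbon_source,
                             cofactors = default_cofactors(),
                             use_gr = TRUE, scope = NULL) {
  gr <- if (use_gr)
    build_gr_constraints(model, groups, carbon_source, cofactors,
                         delta = config$delta, scope = scope)
  else NULL
  scan <- run_scan(model, gr, config)
  candidates <- evaluate_targets(scan, model)
  ranked <- rank_targets(candidates,
                         exclude = c(model$biomass_id, config$target))
  list(gr = gr, scan = scan, candidates = candidates, ranked = ranked)
}
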