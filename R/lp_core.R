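## Solver-facing layer.  Flux balance analysis and flux variability analysis
## are linear programs; grouping-reaction constraints add one binary
## indicator per reaction group (the flux-scale coupling is linear once the
## paired midpoint is expanded, see build_scale()), so the constrained
## problems are small MILPs solved by branch-and-bound on the group binaries
## over a boot::simplex relaxation kernel.

.FEAS_TOL <- 1e-6    # mass-balance feasibility
.BOUND_TOL <- 1e-9   # bound slack
.INT_TOL <- 1e-6     # binary integrality

#' Extra flux constraints for a single solve
#'
#' Overrides applied on top of the model's reaction bounds, e.g. fixing the
#' carbon uptake rate or the enforced product flux.  Overrides replace the
#' model bounds for the named reactions; on/off activation constraints keep
#' using the model's original bounds, so forcing a grouped reaction to zero
#' through an override forces its whole group off whenever the group's
#' original lower bound is positive.
#'
#' @param fixed named numeric vector: reactions fixed to a value (both bounds).
#' @param lower,upper named numeric vectors of replacement bounds.
#' @return A `flux_constraints` object.
#' @export
flux_constraints <- function(fixed = NULL, lower = NULL, upper = NULL) {
  structure(list(fixed = fixed, lower = lower, upper = upper),
            class = "flux_constraints")
}

.apply_constraints <- function(model, extra) {
  lb <- model$reactions$lower; ub <- model$reactions$upper
  names(lb) <- names(ub) <- model$reactions$id
  if (!is.null(extra)) {
    stopifnot(inherits(extra, "flux_constraints"))
    for (set in c("fixed", "lower", "upper")) {
      v <- extra[[set]]
      if (is.null(v)) next
      unknown <- setdiff(names(v), model$reactions$id)
      if (length(unknown) > 0)
        stop("constraint references unknown reaction(s): ",
             paste(unknown, collapse = ", "))
      if (set %in% c("fixed", "lower")) lb[names(v)] <- v
      if (set %in% c("fixed", "upper")) ub[names(v)] <- v
    }
  }
  list(lb = lb, ub = ub)
}

## For members of an on/off group the activation rows y*alpha <= v <= y*beta
## *replace* the static model bounds (otherwise a positive lower bound would
## contradict the off state), so the member's variable bounds are widened to
## include zero -- unless an explicit runtime override pins them.
.grouped_variable_bounds <- function(b, on_off, extra) {
  if (length(on_off) == 0) return(b)
  over_lower <- over_upper <- character(0)
  if (!is.null(extra)) {
    over_lower <- c(names(extra$fixed), names(extra$lower))
    over_upper <- c(names(extra$fixed), names(extra$upper))
  }
  members <- unique(unlist(lapply(on_off, `[[`, "members")))
  relax_lo <- setdiff(members, over_lower)
  relax_hi <- setdiff(members, over_upper)
  b$lb[relax_lo] <- pmin(b$lb[relax_lo], 0)
  b$ub[relax_hi] <- pmax(b$ub[relax_hi], 0)
  b
}

## Assemble the (MI)LP: variables are the reaction fluxes followed by one
## binary per on/off group.  Rows: mass balance (equality for intermediates,
## a net-transport band for extracellular metabolites), on/off activation
## y*alpha_j <= v_j <= y*beta_j, and the flux-scale band
## |v1 - v2| <= delta*sqrt(2)*v_uptake.
.assemble_lp <- function(model, gr = NULL, extra = NULL) {
  ids <- model$reactions$id
  n <- length(ids)
  b <- .apply_constraints(model, extra)
  on_off <- if (is.null(gr)) list() else gr$on_off
  b <- .grouped_variable_bounds(b, on_off, extra)
  scale <- if (is.null(gr)) NULL else gr$scale
  nbin <- length(on_off)
  lb <- c(b$lb, rep(0, nbin))
  ub <- c(b$ub, rep(1, nbin))
  var_ids <- c(ids, if (nbin > 0) paste0(".y.", names(on_off)) else character(0))

  met <- model$metabolites
  S <- as.matrix(model$S)
  balanced <- !met$boundary
  eq_rows <- balanced & (abs(met$upper - met$lower) <= .BOUND_TOL)
  band_rows <- balanced & !eq_rows

  pad <- function(A) cbind(A, matrix(0, nrow(A), nbin))
  Aeq <- pad(S[eq_rows, , drop = FALSE])
  beq <- met$lower[eq_rows]

  Ale <- matrix(0, 0, n + nbin); ble <- numeric(0)
  if (any(band_rows)) {
    Sb <- pad(S[band_rows, , drop = FALSE])
    Ale <- rbind(Ale, Sb, -Sb)
    ble <- c(ble, met$upper[band_rows], -met$lower[band_rows])
  }
  if (nbin > 0) {
    for (g in seq_along(on_off)) {
      cpl <- on_off[[g]]
      for (k in seq_along(cpl$members)) {
        j <- match(cpl$members[k], ids)
        up <- numeric(n + nbin); up[j] <- 1; up[n + g] <- -cpl$upper[k]
        lo <- numeric(n + nbin); lo[j] <- -1; lo[n + g] <- cpl$lower[k]
        Ale <- rbind(Ale, up, lo)
        ble <- c(ble, 0, 0)
      }
    }
  }
  if (!is.null(scale) && nrow(scale) > 0) {
    if (is.na(model$uptake_id))
      stop("flux-scale couplings require the model's carbon uptake reaction")
    u <- match(model$uptake_id, ids)
    for (k in seq_len(nrow(scale))) {
      j1 <- match(scale$r1[k], ids); j2 <- match(scale$r2[k], ids)
      cc <- scale$delta[k] * sqrt(2)
      r1 <- numeric(n + nbin); r1[j1] <- 1; r1[j2] <- -1; r1[u] <- r1[u] - cc
      r2 <- numeric(n + nbin); r2[j2] <- 1; r2[j1] <- -1; r2[u] <- r2[u] - cc
      Ale <- rbind(Ale, r1, r2)
      ble <- c(ble, 0, 0)
    }
  }
  rownames(Ale) <- NULL
  list(n = n, nbin = nbin, var_ids = var_ids, lb = lb, ub = ub,
       Aeq = Aeq, beq = beq, Ale = Ale, ble = ble,
       int_idx = if (nbin > 0) n + seq_len(nbin) else integer(0))
}

## LP presolve shared by both kernels: tightens singleton rows into variable
## bounds, substitutes fixed variables into the right-hand sides, and drops
## empty rows.  This removes the degenerate zero-width rows that make both
## installed simplex codes stall or divide 0/0 (e.g. on/off activation rows
## once the group binary is pinned).
.lp_presolve <- function(lb, ub, Aeq, beq, Ale, ble) {
  infeasible <- list(infeasible = TRUE)
  repeat {
    if (any(lb > ub + .BOUND_TOL)) return(infeasible)
    changed <- FALSE
    if (nrow(Ale) > 0) {
      nz <- abs(Ale) > 1e-12
      cnt <- rowSums(nz)
      if (any(cnt == 0)) {
        if (any(ble[cnt == 0] < -.FEAS_TOL)) return(infeasible)
        keep <- cnt > 0
        Ale <- Ale[keep, , drop = FALSE]; ble <- ble[keep]
        next
      }
      sg <- which(cnt == 1)
      if (length(sg) > 0) {
        for (r in sg) {
          j <- which(nz[r, ]); a <- Ale[r, j]; v <- ble[r] / a
          if (a > 0) ub[j] <- min(ub[j], v) else lb[j] <- max(lb[j], v)
        }
        Ale <- Ale[-sg, , drop = FALSE]; ble <- ble[-sg]
        next
      }
    }
    if (nrow(Aeq) > 0) {
      nz <- abs(Aeq) > 1e-12
      cnt <- rowSums(nz)
      if (any(cnt == 0)) {
        if (any(abs(beq[cnt == 0]) > .FEAS_TOL)) return(infeasible)
        keep <- cnt > 0
        Aeq <- Aeq[keep, , drop = FALSE]; beq <- beq[keep]
        next
      }
      sg <- which(cnt == 1)
      if (length(sg) > 0) {
        for (r in sg) {
          j <- which(nz[r, ]); v <- beq[r] / Aeq[r, j]
          if (v < lb[j] - .FEAS_TOL || v > ub[j] + .FEAS_TOL) return(infeasible)
          lb[j] <- max(lb[j], min(v, ub[j]))
          ub[j] <- min(ub[j], max(v, lb[j]))
        }
        Aeq <- Aeq[-sg, , drop = FALSE]; beq <- beq[-sg]
        next
      }
    }
    ## forcing rows: a row whose achievable extreme equals its right-hand
    ## side pins every participating variable at the matching bound
    row_extremes <- function(A) {
      pos <- pmax(A, 0); negm <- pmin(A, 0)
      list(rmin = as.numeric(pos %*% lb + negm %*% ub),
           rmax = as.numeric(pos %*% ub + negm %*% lb))
    }
    pin_at <- function(arow, at_min) {
      for (j in which(abs(arow) > 1e-12)) {
        v <- if (xor(arow[j] > 0, at_min)) ub[j] else lb[j]
        lb[j] <<- v; ub[j] <<- v
      }
    }
    if (nrow(Aeq) > 0) {
      e <- row_extremes(Aeq)
      if (any(beq < e$rmin - .FEAS_TOL | beq > e$rmax + .FEAS_TOL))
        return(infeasible)
      force_min <- abs(beq - e$rmin) <= .FEAS_TOL & e$rmax > e$rmin + .FEAS_TOL
      force_max <- abs(beq - e$rmax) <= .FEAS_TOL & e$rmax > e$rmin + .FEAS_TOL
      if (any(force_min | force_max)) {
        for (r in which(force_min)) pin_at(Aeq[r, ], at_min = TRUE)
        for (r in which(force_max)) pin_at(Aeq[r, ], at_min = FALSE)
        keep <- !(force_min | force_max)
        Aeq <- Aeq[keep, , drop = FALSE]; beq <- beq[keep]
        next
      }
    }
    if (nrow(Ale) > 0) {
      e <- row_extremes(Ale)
      if (any(ble < e$rmin - .FEAS_TOL)) return(infeasible)
      redundant <- e$rmax <= ble + .FEAS_TOL
      force_min <- abs(ble - e$rmin) <= .FEAS_TOL & !redundant
      if (any(redundant | force_min)) {
        for (r in which(force_min)) pin_at(Ale[r, ], at_min = TRUE)
        keep <- !(redundant | force_min)
        Ale <- Ale[keep, , drop = FALSE]; ble <- ble[keep]
        next
      }
    }
    fixed <- (ub - lb) <= .BOUND_TOL
    in_rows <- (if (nrow(Aeq) > 0) colSums(abs(Aeq) > 1e-12) else 0) +
      (if (nrow(Ale) > 0) colSums(abs(Ale) > 1e-12) else 0)
    active <- which(fixed & in_rows > 0)
    if (length(active) > 0) {
      xf <- (lb + ub) / 2
      if (nrow(Aeq) > 0) {
        beq <- as.numeric(beq - Aeq[, active, drop = FALSE] %*% xf[active])
        Aeq[, active] <- 0
      }
      if (nrow(Ale) > 0) {
        ble <- as.numeric(ble - Ale[, active, drop = FALSE] %*% xf[active])
        Ale[, active] <- 0
      }
      next
    }
    if (!changed) break
  }
  list(infeasible = FALSE, lb = lb, ub = ub,
       Aeq = Aeq, beq = beq, Ale = Ale, ble = ble)
}

## LP kernel over boot::simplex.  Variables are shifted to x >= 0 after the
## presolve; equality rows are sign-normalised to a non-negative right-hand
## side, general inequalities are routed to the <= or >= blocks by the sign
## of their shifted right-hand side.
.lp_boot <- function(obj, lb, ub, Aeq, beq, Ale, ble, sense) {
  p <- .lp_presolve(lb, ub, as.matrix(Aeq), beq, as.matrix(Ale), ble)
  if (p$infeasible)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  lb <- p$lb; ub <- p$ub
  fixed <- (ub - lb) <= .BOUND_TOL
  xfix <- (lb + ub) / 2
  if (all(fixed))   # presolve solved it outright
    return(list(status = "optimal", objective = sum(obj * xfix), x = xfix))
  free <- which(!fixed)
  A3 <- p$Aeq[, free, drop = FALSE]
  Af <- p$Ale[, free, drop = FALSE]
  sh <- lb[free]
  b3 <- p$beq - as.numeric(A3 %*% sh)
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]; b3[neg] <- -b3[neg]
  A1 <- diag(length(free)); b1 <- ub[free] - sh
  A2 <- NULL; b2 <- NULL
  if (nrow(Af) > 0) {
    bf <- p$ble - as.numeric(Af %*% sh)
    pos <- bf >= 0
    if (any(pos)) { A1 <- rbind(A1, Af[pos, , drop = FALSE]); b1 <- c(b1, bf[pos]) }
    if (any(!pos)) { A2 <- -Af[!pos, , drop = FALSE]; b2 <- -bf[!pos] }
  }
  niter <- 200 * (length(free) + length(b1) + length(b2) + length(b3))
  a <- obj[free]
  if (all(abs(a) < 1e-12)) a <- rep(1, length(free))  # pure feasibility check
  s <- tryCatch(
    boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = if (nrow(A3) > 0) A3 else NULL,
                  b3 = if (nrow(A3) > 0) b3 else NULL,
                  maxi = (sense == "max"), n.iter = niter),
    error = function(e) NULL)
  if (is.null(s))
    return(list(status = "failed", objective = NA_real_, x = NULL))
  if (s$solved == -1)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  if (s$solved != 1)
    return(list(status = "failed", objective = NA_real_, x = NULL))
  x <- xfix
  x[free] <- s$soln + sh
  list(status = "optimal", objective = sum(obj * x), x = x)
}

## Branch-and-bound over the group binaries; the relaxation keeps each
## binary continuous in [0,1].  Groups are few and small, so the tree is
## tiny; no warm starting is needed for correctness or speed here.
.milp_boot <- function(obj, lb, ub, Aeq, beq, Ale, ble, int_idx, sense) {
  if (length(int_idx) == 0)
    return(.lp_boot(obj, lb, ub, Aeq, beq, Ale, ble, sense))
  sgn <- if (sense == "max") 1 else -1
  best <- NULL
  bestval <- -Inf
  recurse <- function(lb, ub) {
    r <- .lp_boot(obj, lb, ub, Aeq, beq, Ale, ble, sense)
    if (r$status == "failed") stop("LP relaxation failed to converge")
    if (r$status != "optimal") return(invisible(NULL))
    relax <- sgn * r$objective
    if (!is.null(best) && relax <= bestval + 1e-9) return(invisible(NULL))
    y <- r$x[int_idx]
    frac <- abs(y - round(y))
    if (all(frac <= .INT_TOL)) {
      if (relax > bestval) { best <<- r; bestval <<- relax }
      return(invisible(NULL))
    }
    k <- int_idx[which.max(frac)]
    lb0 <- lb; ub0 <- ub; ub0[k] <- 0
    recurse(lb0, ub0)
    lb1 <- lb; ub1 <- ub; lb1[k] <- 1
    recurse(lb1, ub1)
    invisible(NULL)
  }
  recurse(lb, ub)
  if (is.null(best))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  best$x[int_idx] <- round(best$x[int_idx])
  best
}

.solve_prob <- function(prob, obj, sense) {
  .milp_boot(obj, prob$lb, prob$ub, prob$Aeq, prob$beq, prob$Ale, prob$ble,
             prob$int_idx, sense)
}

.obj_vector <- function(prob, reaction) {
  j <- match(reaction, prob$var_ids)
  if (is.na(j)) stop("unknown reaction '", reaction, "'")
  obj <- numeric(length(prob$var_ids))
  obj[j] <- 1
  obj
}

#' Flux balance analysis
#'
#' Optimises a single reaction flux subject to steady-state mass balance,
#' reaction bounds, optional grouping-reaction constraints and optional extra
#' constraints.  Alternative optima are returned as-is: downstream analysis
#' works on flux *ranges*, never on one arbitrary optimal vertex.
#'
#' @param model a [metabolic_model()].
#' @param objective reaction id to optimise; default the biomass reaction.
#' @param sense `"max"` or `"min"`.
#' @param gr optional [gr_constraint_set()].
#' @param extra optional [flux_constraints()].
#' @return A `flux_distribution`: list with `fluxes` (named vector),
#'   `binaries` (named 0/1 vector, one per on/off group), `objective_value`
#'   and `status` (`"optimal"`/`"infeasible"`).  Infeasibility is reported in
#'   `status`, never silently clipped.
#' @export
solve_fba <- function(model, objective = NULL, sense = c("max", "min"),
                      gr = NULL, extra = NULL) {
  sense <- match.arg(sense)
  if (is.null(objective)) objective <- model$biomass_id
  if (is.na(objective)) stop("no objective reaction given and no biomass reaction set")
  prob <- .assemble_lp(model, gr, extra)
  r <- .solve_prob(prob, .obj_vector(prob, objective), sense)
  fluxes <- binaries <- NULL
  if (r$status == "optimal") {
    fluxes <- r$x[seq_len(prob$n)]
    names(fluxes) <- model$reactions$id
    if (prob$nbin > 0) {
      binaries <- r$x[prob$int_idx]
      names(binaries) <- sub("^\\.y\\.", "", prob$var_ids[prob$int_idx])
    }
  }
  structure(list(fluxes = fluxes, binaries = binaries,
                 objective_value = r$objective, status = r$status,
                 objective = objective, sense = sense),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution:", x$sense, x$objective, "=",
      format(x$objective_value), "(", x$status, ")\n")
  invisible(x)
}

#' Feasible flux range of one reaction
#'
#' Minimises then maximises the reaction's flux under all active constraints
#' (the flux variability analysis primitive).
#'
#' @inheritParams solve_fba
#' @param reaction reaction id.
#' @return list with `reaction_id`, `v_min`, `v_max`, `status_min`,
#'   `status_max`.  When the base problem is infeasible both statuses say so.
#' @export
flux_range <- function(model, reaction, gr = NULL, extra = NULL) {
  prob <- .assemble_lp(model, gr, extra)
  obj <- .obj_vector(prob, reaction)
  lo <- .solve_prob(prob, obj, "min")
  hi <- .solve_prob(prob, obj, "max")
  list(reaction_id = reaction, v_min = lo$objective, v_max = hi$objective,
       status_min = lo$status, status_max = hi$status)
}

#' Flux variability analysis over a set of reactions
#'
#' @inheritParams solve_fba
#' @param reactions reaction ids to sweep; default all intracellular
#'   (non-exchange) reactions.
#' @return data.frame with one row per reaction: `reaction_id`, `v_min`,
#'   `v_max`, `status_min`, `status_max`.
#' @export
fva <- function(model, reactions = NULL, gr = NULL, extra = NULL) {
  if (is.null(reactions))
    reactions <- model$reactions$id[!model$reactions$exchange]
  prob <- .assemble_lp(model, gr, extra)
  rows <- lapply(reactions, function(rid) {
    obj <- .obj_vector(prob, rid)
    lo <- .solve_prob(prob, obj, "min")
    hi <- .solve_prob(prob, obj, "max")
    data.frame(reaction_id = rid, v_min = lo$objective, v_max = hi$objective,
               status_min = lo$status, status_max = hi$status)
  })
  do.call(rbind, rows)
}

#' Minimal and theoretical maximal product flux
#'
#' With the carbon-source uptake fixed to the configured rate, minimises and
#' maximises the target product flux under grouping-reaction constraints.
#' These two extremes anchor the enforced-flux scan schedule.
#'
#' @inheritParams solve_fba
#' @param target target product reaction id.
#' @param uptake_rate carbon uptake rate (mmol/gDCW/h) the uptake reaction is
#'   fixed to.
#' @return named numeric vector `c(v_initial, v_max)`.
#' @export
product_flux_extremes <- function(model, target, gr = NULL, uptake_rate = 10) {
  if (is.na(model$uptake_id))
    stop("model has no carbon uptake reaction set")
  extra <- flux_constraints(fixed = stats::setNames(uptake_rate, model$uptake_id))
  prob <- .assemble_lp(model, gr, extra)
  obj <- .obj_vector(prob, target)
  lo <- .solve_prob(prob, obj, "min")
  hi <- .solve_prob(prob, obj, "max")
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("product flux extremes infeasible for target '", target,
         "' (uptake ", uptake_rate, ", min: ", lo$status,
         ", max: ", hi$status, ")")
  c(v_initial = lo$objective, v_max = hi$objective)
}

#' Check steady-state mass balance of a flux vector
#'
#' @param model a `metabolic_model`.
#' @param fluxes named flux vector over all reactions.
#' @param tol feasibility tolerance.
#' @return Maximum absolute mass-balance residual over balanced intermediates
#'   (invisibly `TRUE`/`FALSE` attribute-free; returns the residual).
#' @export
mass_balance_residual <- function(model, fluxes, tol = .FEAS_TOL) {
  met <- model$metabolites
  keep <- !met$boundary & abs(met$upper - met$lower) <= .BOUND_TOL
  res <- as.numeric(model$S[keep, , drop = FALSE] %*%
                      fluxes[model$reactions$id]) - met$lower[keep]
  max(abs(res))
}
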