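## Toy metabolic networks with hand-computable behaviour, plus a brute-force
## oracle that verifies the branch-and-bound layer by exhaustive enumeration
## of the on/off binary patterns over an independent LP kernel
## (pracma::linprog, a different simplex implementation than the one the
## production solver uses).

#' Generate a toy metabolic network
#'
#' Three topologies with known analytic behaviour:
#'
#' * `linear_chain`: `n` reactions in series between two boundary species;
#'   every internal flux equals the uptake.  No groups.
#' * `diamond`: a split at one metabolite and a rejoin at another (the
#'   minimal flux-converging motif), with one on/off group on one branch.
#' * `glycolysis_like`: glucose-style C6 uptake, an aldolase-style split of a
#'   C6 into two trioses, a rejoin at a glyceraldehyde-3-phosphate analogue
#'   (the single flux-converging metabolite), phosphoenolpyruvate and
#'   pyruvate intermediates, two isoenzyme-style parallel pyruvate kinases, a
#'   product branch drawing on pyruvate, a biomass drain competing for the
#'   same precursors, and a pyruvate-overflow secretion.  Ships with an
#'   on/off group on the split-rejoin pair and a second group on the
#'   isoenzyme pair (whose equal CxJy indices also yield a flux-scale
#'   coupling).  With uptake 10 the theoretical product maximum is 20
#'   (complete C6 -> 2 x C3 routing) and the optimal growth at enforced
#'   product flux `p` is `(20 - p)/2`.
#'
#' @param topology one of `"linear_chain"`, `"diamond"`, `"glycolysis_like"`.
#' @param n number of reactions for `linear_chain`.
#' @param uptake_cap upper bound of the uptake reaction (the scan fixes the
#'   uptake to its configured rate; this is the physiological cap).
#' @param seed optional seed; when given, the upper bounds of the internal
#'   reactions are perturbed uniformly in \[30, 1000\] (never below the
#'   carbon-limited maximum flux, so every analytic yield is preserved and
#'   stoichiometry is never touched).
#' @return list with `model` (a [metabolic_model()]) and `groups` (a
#'   [reaction_groups()] object).
#' @export
make_toy_model <- function(topology = c("glycolysis_like", "linear_chain", "diamond"),
                           n = 3, uptake_cap = 10, seed = NULL) {
  topology <- match.arg(topology)
  fix <- switch(topology,
                linear_chain = .toy_linear_chain(n, uptake_cap),
                diamond = .toy_diamond(uptake_cap),
                glycolysis_like = .toy_glycolysis(uptake_cap))
  if (!is.null(seed)) {
    set.seed(seed)
    r <- fix$model$reactions
    internal <- !r$exchange & r$id != fix$model$biomass_id
    r$upper[internal] <- round(stats::runif(sum(internal), 30, 1000), 3)
    fix$model$reactions <- r
    validate_model(fix$model)
  }
  fix
}

.toy_linear_chain <- function(n, uptake_cap) {
  stopifnot(n >= 2)
  internal <- paste0("m", seq_len(n - 1))
  mets <- data.frame(id = c("b_src", internal, "b_out"),
                     formula = "C6H12O6",
                     compartment = c("e", rep("c", n - 1), "e"),
                     extracellular = c(TRUE, rep(FALSE, n - 1), TRUE),
                     boundary = c(TRUE, rep(FALSE, n - 1), TRUE))
  chain <- c("b_src", internal, "b_out")
  rids <- paste0("R", seq_len(n))
  sto <- lapply(seq_len(n), function(i)
    stats::setNames(c(-1, 1), chain[c(i, i + 1)]))
  names(sto) <- rids
  rx <- data.frame(id = rids, lower = 0,
                   upper = c(uptake_cap, rep(1000, n - 1)),
                   reversible = FALSE,
                   exchange = c(TRUE, rep(FALSE, n - 2), TRUE))
  model <- metabolic_model(mets, rx, sto, biomass = rids[n], uptake = rids[1])
  groups <- reaction_groups(data.frame(group_id = character(0),
                                       reaction_id = character(0),
                                       evidence = character(0)))
  list(model = model, groups = groups)
}

.toy_diamond <- function(uptake_cap) {
  mets <- data.frame(
    id = c("b_src", "A", "B", "C", "D", "b_out", "b_leak"),
    formula = "C6H12O6",
    compartment = c("e", "c", "c", "c", "c", "e", "e"),
    extracellular = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  sto <- list(
    R_upt = c(b_src = -1, A = 1),
    R1 = c(A = -1, B = 1),
    R2 = c(A = -1, C = 1),
    R3 = c(B = -1, D = 1),
    R4 = c(C = -1, D = 1),
    R_out = c(D = -1, b_out = 1),
    R_leak = c(A = -1, b_leak = 1))   # overflow so a 95% growth line is feasible
  rx <- data.frame(id = names(sto), lower = 0,
                   upper = c(uptake_cap, 1000, 1000, 1000, 1000, 1000, 1000),
                   reversible = FALSE,
                   exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  model <- metabolic_model(mets, rx, sto, biomass = "R_out", uptake = "R_upt")
  groups <- reaction_groups(data.frame(group_id = "G1",
                                       reaction_id = c("R1", "R3"),
                                       evidence = "neighborhood"))
  list(model = model, groups = groups)
}

.toy_glycolysis <- function(uptake_cap) {
  mets <- data.frame(
    id = c("b_glc", "glc", "f6p", "dhap", "g3p", "pep", "pyr", "prod",
           "b_prod", "b_pyr", "atp", "adp"),
    formula = c("C6H12O6", "C6H12O6", "C6H13O9P", "C3H7O6P", "C3H7O6P",
                "C3H5O6P", "C3H4O3", "C3H6O3", "C3H6O3", "C3H4O3",
                "C10H16N5O13P3", "C10H15N5O10P2"),
    compartment = c("e", rep("c", 7), "e", "e", "c", "c"),
    extracellular = c(TRUE, rep(FALSE, 7), TRUE, TRUE, FALSE, FALSE),
    boundary = c(TRUE, rep(FALSE, 7), TRUE, TRUE, TRUE, TRUE))
  sto <- list(
    R_upt = c(b_glc = -1, glc = 1),
    R_pgi = c(glc = -1, atp = -1, f6p = 1, adp = 1),
    R_fba = c(f6p = -1, dhap = 1, g3p = 1),
    R_tpi = c(dhap = -1, g3p = 1),
    R_gap = c(g3p = -1, pep = 1),
    R_pyk = c(pep = -1, pyr = 1),
    R_alt = c(pep = -1, pyr = 1),
    R_prod = c(pyr = -1, prod = 1),
    R_bio = c(pep = -1, pyr = -1),
    R_exprod = c(prod = -1, b_prod = 1),
    R_expyr = c(pyr = -1, b_pyr = 1))
  rx <- data.frame(
    id = names(sto), lower = 0,
    upper = c(uptake_cap, rep(1000, 10)),
    reversible = FALSE,
    exchange = c(TRUE, rep(FALSE, 8), TRUE, TRUE),
    genes = c("", "glk", "fbaA", "tpiA", "gapA", "pykF", "pykA",
              "prodX", "", "", ""))
  model <- metabolic_model(mets, rx, sto, biomass = "R_bio", uptake = "R_upt")
  groups <- reaction_groups(data.frame(
    group_id = c("G1", "G1", "G2", "G2"),
    reaction_id = c("R_fba", "R_tpi", "R_pyk", "R_alt"),
    evidence = c("neighborhood", "neighborhood", "cooccurrence", "cooccurrence")))
  list(model = model, groups = groups)
}

#' Write a toy fixture as SBML plus a groups TSV
#'
#' Exercises the real I/O path: the files can be read back with
#' [read_sbml()] and [read_groups()].
#'
#' @param fixture list from [make_toy_model()].
#' @param dir output directory (created if missing).
#' @return named character vector with the `model` and `groups` paths.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model_path <- file.path(dir, "model.xml")
  groups_path <- file.path(dir, "groups.tsv")
  write_sbml(fixture$model, model_path)
  write_groups(fixture$groups, groups_path)
  c(model = model_path, groups = groups_path)
}

## Independent LP kernel: pracma::linprog in standard form (x >= 0, equality
## rows only, slack variables for every inequality), fixed variables
## eliminated by substitution.  Deliberately a different code path and a
## different simplex implementation than the production kernel.
.lp_pracma <- function(obj, lb, ub, Aeq, beq, Ale, ble, sense) {
  if (any(lb > ub + 1e-9))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  fixed <- (ub - lb) <= 1e-9
  xfix <- (lb + ub) / 2
  if (all(fixed)) {
    ok <- (length(beq) == 0 || all(abs(Aeq %*% xfix - beq) <= 1e-6)) &&
      (length(ble) == 0 || all(Ale %*% xfix - ble <= 1e-6))
    return(list(status = if (ok) "optimal" else "infeasible",
                objective = if (ok) sum(obj * xfix) else NA_real_,
                x = if (ok) xfix else NULL))
  }
  free <- which(!fixed)
  nf <- length(free)
  sh <- lb[free]
  fold <- function(A, rhs) {
    if (length(rhs) == 0) return(list(A = matrix(0, 0, nf), b = numeric(0)))
    list(A = A[, free, drop = FALSE],
         b = as.numeric(rhs - A[, fixed, drop = FALSE] %*% xfix[fixed] -
                          A[, free, drop = FALSE] %*% sh))
  }
  eq <- fold(Aeq, beq)
  le <- fold(Ale, ble)
  ## upper-bound rows join the inequality block
  ub_rows <- diag(nf)
  le$A <- rbind(le$A, ub_rows)
  le$b <- c(le$b, ub[free] - sh)
  nslack <- nrow(le$A)
  A <- rbind(cbind(eq$A, matrix(0, nrow(eq$A), nslack)),
             cbind(le$A, diag(nslack)))
  b <- c(eq$b, le$b)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  sgn <- if (sense == "max") -1 else 1
  cc <- c(sgn * obj[free], rep(0, nslack))
  r <- suppressWarnings(
    tryCatch(pracma::linprog(cc = cc, Aeq = A, beq = b, maxiter = 10000,
                             bigM = 1e4),
             error = function(e) list(errno = -99)))
  if (!identical(r$errno, 1))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  x <- xfix
  x[free] <- r$x[seq_len(nf)] + sh
  list(status = "optimal", objective = sum(obj * x), x = x)
}

#' Brute-force flux-range oracle
#'
#' Enumerates every on/off binary assignment consistent with the group ties
#' (one binary per group), applies the implied bounds per pattern together
#' with the flux-scale bands, solves the continuous min/max with an
#' independent LP kernel, and returns the outer envelope over all feasible
#' patterns -- exact by construction, used to verify the branch-and-bound
#' layer.
#'
#' @inheritParams flux_range
#' @return list with `reaction_id`, `v_min`, `v_max`, `status_min`,
#'   `status_max`, and `n_feasible_patterns`.
#' @export
brute_force_fva_oracle <- function(model, reaction, gr = NULL, extra = NULL) {
  on_off <- if (is.null(gr)) list() else gr$on_off
  ngrp <- length(on_off)
  if (2^ngrp > 65536) stop("too many on/off patterns to enumerate")
  bnds <- .grouped_variable_bounds(.apply_constraints(model, extra),
                                   on_off, extra)
  ids <- model$reactions$id
  met <- model$metabolites
  S <- as.matrix(model$S)
  balanced <- !met$boundary
  eq_rows <- balanced & (abs(met$upper - met$lower) <= 1e-9)
  Aeq <- S[eq_rows, , drop = FALSE]; beq <- met$lower[eq_rows]
  Ale <- matrix(0, 0, length(ids)); ble <- numeric(0)
  band <- balanced & !eq_rows
  if (any(band)) {
    Sb <- S[band, , drop = FALSE]
    Ale <- rbind(Ale, Sb, -Sb)
    ble <- c(ble, met$upper[band], -met$lower[band])
  }
  scale <- if (is.null(gr)) NULL else gr$scale
  if (!is.null(scale) && nrow(scale) > 0) {
    u <- match(model$uptake_id, ids)
    for (k in seq_len(nrow(scale))) {
      j1 <- match(scale$r1[k], ids); j2 <- match(scale$r2[k], ids)
      cc <- scale$delta[k] * sqrt(2)
      r1 <- numeric(length(ids)); r1[j1] <- 1; r1[j2] <- -1; r1[u] <- r1[u] - cc
      r2 <- -r1; r2[u] <- r1[u]
      Ale <- rbind(Ale, r1, r2); ble <- c(ble, 0, 0)
    }
  }
  obj <- numeric(length(ids))
  obj[match(reaction, ids)] <- 1

  patterns <- if (ngrp == 0) matrix(1, 1, 0) else
    as.matrix(expand.grid(rep(list(c(0, 1)), ngrp)))
  v_min <- Inf; v_max <- -Inf; feasible <- 0
  for (p in seq_len(nrow(patterns))) {
    lb <- bnds$lb; ub <- bnds$ub
    ok <- TRUE
    for (g in seq_len(ngrp)) {
      cpl <- on_off[[g]]
      j <- match(cpl$members, ids)
      if (patterns[p, g] == 1) {        # y = 1: original activation bounds
        lb[j] <- pmax(lb[j], cpl$lower)
        ub[j] <- pmin(ub[j], cpl$upper)
      } else {                          # y = 0: all members carry zero flux
        lb[j] <- pmax(lb[j], 0)
        ub[j] <- pmin(ub[j], 0)
      }
    }
    if (any(lb > ub + 1e-9)) next
    lo <- .lp_pracma(obj, lb, ub, Aeq, beq, Ale, ble, "min")
    if (lo$status != "optimal") next
    hi <- .lp_pracma(obj, lb, ub, Aeq, beq, Ale, ble, "max")
    if (hi$status != "optimal") next
    feasible <- feasible + 1
    v_min <- min(v_min, lo$objective)
    v_max <- max(v_max, hi$objective)
  }
  if (feasible == 0)
    return(list(reaction_id = reaction, v_min = NA_real_, v_max = NA_real_,
                status_min = "infeasible", status_max = "infeasible",
                n_feasible_patterns = 0L))
  list(reaction_id = reaction, v_min = v_min, v_max = v_max,
       status_min = "optimal", status_max = "optimal",
       n_feasible_patterns = as.integer(feasible))
}
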