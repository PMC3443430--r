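test_that("flux-converging metabolites are split-rejoin points only", {
  # diamond: A splits to B/C which rejoin at D
  dia <- make_toy_model("diamond")$model
  expect_equal(find_flux_converging_metabolites(dia, "A"), "D")
  # pure linear chain: nothing splits
  chain <- make_toy_model("linear_chain", n = 4)$model
  expect_equal(find_flux_converging_metabolites(chain, "m1"), character(0))
  # glycolysis-like: the triose rejoins the aldolase split (G3P analogue)
  gly <- glyco()$model
  expect_equal(find_flux_converging_metabolites(gly, "glc"), "g3p")
  # unreachable carbon source warns and returns empty
  expect_warning(out <- find_flux_converging_metabolites(gly, "prod"),
                 "reaches no other")
  expect_equal(out, character(0))
})

test_that("carbon index sums primary carbons and halves them, excluding cofactors", {
  gly <- glyco()$model
  # C6 -> C6: N_C = 12, x = 6 (ATP/ADP on the reaction are excluded)
  ci <- carbon_index(gly, "R_pgi")
  expect_equal(ci$n_c, 12)
  expect_equal(ci$x, 6)
  # split C6 -> C3 + C3 keeps N_C = 12
  expect_equal(carbon_index(gly, "R_fba")$n_c, 12)
  # C3 -> C3: N_C = 6, x = 3
  expect_equal(carbon_index(gly, "R_tpi"), list(n_c = 6, x = 3))
  # with cofactors counted the hexokinase-like step would carry 10+10 extra carbons
  ci_all <- carbon_index(gly, "R_pgi", cofactors = character(0))
  expect_equal(ci_all$n_c, 32)
  # unparseable primary formula marks the reaction unindexable
  m <- gly
  m$metabolites$formula[m$metabolites$id == "f6p"] <- "C6H11O9PR"
  expect_true(is.na(carbon_index(m, "R_fba")$n_c))
})

test_that("CxJy assignment tags routes by convergers passed and pyruvate origin", {
  fix <- glyco()
  idx <- assign_cxjy(fix$model, "glc")
  entry <- function(rid) idx$entries[idx$reaction_id == rid]
  # first reactions after the source: no converger passed yet
  expect_equal(entry("R_pgi"), "C6JA")
  expect_equal(entry("R_fba"), "C6JA")
  # G3P itself is the converger: strictly-upstream counting keeps its consumer at A
  expect_equal(entry("R_gap"), "C3JA")
  # one converger (G3P) lies on every route to PEP
  expect_equal(entry("R_pyk"), "C3JB")
  expect_equal(entry("R_alt"), "C3JB")
  # flux through pyruvate carries the E suffix
  expect_equal(entry("R_prod"), "C3JBE")
  # biomass draws on PEP (B) and pyruvate (BE): slash-partitioned entries
  expect_equal(entry("R_bio"), "C3JB/C3JBE")
  # reactions whose substrates have no route from the source are unindexable
  expect_false(idx$indexable[idx$reaction_id == "R_upt"])
})

test_that("CxJy assignment is a pure function of the digraph (deterministic)", {
  fix <- glyco()
  a <- assign_cxjy(fix$model, "glc")
  b <- assign_cxjy(fix$model, "glc")
  expect_identical(a, b)
})

test_that("multi-route reactions collect one tag per distinct converger count", {
  # two routes to the substrate of R_t: direct (0 convergers) and through the
  # rejoin D (1 converger): slash-partitioned {A, B}
  mets <- data.frame(id = c("b_s", "A", "B", "C", "D", "E", "b_o"),
                     formula = "C6H12O6",
                     boundary = c(TRUE, rep(FALSE, 5), TRUE))
  sto <- list(R_in = c(b_s = -1, A = 1),
              R1 = c(A = -1, B = 1), R2 = c(A = -1, C = 1),
              R3 = c(B = -1, D = 1), R4 = c(C = -1, D = 1),
              R5 = c(D = -1, E = 1), R6 = c(A = -1, E = 1),
              R_t = c(E = -1, b_o = 1))
  rx <- data.frame(id = names(sto))
  rx$exchange <- rx$id %in% c("R_in", "R_t")
  m <- metabolic_model(mets, rx, sto, biomass = "R_t", uptake = "R_in")
  idx <- assign_cxjy(m, "A")
  expect_equal(idx$entries[idx$reaction_id == "R_t"], "C6JA/C6JB")
})

test_that("on/off couplings force grouped reactions off together", {
  dia <- make_toy_model("diamond")
  m <- dia$model
  m$reactions$lower[m$reactions$id == "R1"] <- 2   # active means >= 2
  groups <- reaction_groups(data.frame(group_id = "G", reaction_id = c("R1", "R4"),
                                       evidence = "manual"))
  gr <- gr_constraint_set(on_off = build_on_off(groups, m))
  ex <- flux_constraints(fixed = c(R_upt = 10), upper = c(R1 = 0))
  # R1 shut by an override conflicts with its activation lower bound, so the
  # shared binary drops and R4 collapses with it
  r <- flux_range(m, "R4", gr = gr, extra = ex)
  expect_range_equal(r, 0, 0)
  # without the coupling R4 still carries up to the full uptake (the plain
  # model needs R1 shut outright, since its static lower bound is 2)
  r_free <- flux_range(m, "R4", extra = flux_constraints(fixed = c(R_upt = 10,
                                                                   R1 = 0)))
  expect_range_equal(r_free, 0, 10)
  # with the binary on, member ranges equal the unconstrained ranges
  ex_on <- flux_constraints(fixed = c(R_upt = 10), lower = c(R1 = 2))
  r_on_gr <- flux_range(m, "R4", gr = gr, extra = ex_on)
  r_on_plain <- flux_range(m, "R4", extra = ex_on)
  expect_equal(r_on_gr$v_min, r_on_plain$v_min, tolerance = 1e-6)
  expect_equal(r_on_gr$v_max, r_on_plain$v_max, tolerance = 1e-6)
})

test_that("scale couplings pair only index-equivalent group members", {
  fix <- glyco()
  idx <- assign_cxjy(fix$model, "glc")
  sc <- build_scale(fix$groups, idx, delta = 0.3)
  # {R_pyk, R_alt} share C3JB; {R_fba (C6JA), R_tpi (C3JA)} differ
  expect_equal(nrow(sc), 1L)
  expect_setequal(c(sc$r1, sc$r2), c("R_pyk", "R_alt"))
  expect_equal(sc$delta, 0.3)
  # an unindexable member skips the pair with a warning
  m <- fix$model
  m$metabolites$formula[m$metabolites$id == "dhap"] <- NA
  idx2 <- assign_cxjy(m, "glc")
  expect_warning(sc2 <- build_scale(fix$groups, idx2, delta = 0.3),
                 "unindexable")
  expect_equal(nrow(sc2), 1L)  # the pyk/alt pair survives
})

test_that("the scale coupling left-hand side matches its definition", {
  # midpoint deviations +-0.5 give sqrt(0.25 + 0.25)
  expect_equal(scale_coupling_lhs(1, 0), sqrt(0.5))
  expect_gt(scale_coupling_lhs(1, 0), 0.3)     # rejected at delta = 0.3
  expect_equal(scale_coupling_lhs(0.5, 0.5), 0) # symmetric point accepted
  # the linear band used by the solver is exactly equivalent for a pair
  v1 <- runif(50, -2, 2); v2 <- runif(50, -2, 2)
  expect_equal(scale_coupling_lhs(v1, v2) <= 0.3,
               abs(v1 - v2) <= 0.3 * sqrt(2))
})

test_that("scale couplings reject unbalanced pairs at the solver level", {
  fix <- glyco()
  gr <- glyco_gr(fix)
  # normalised fluxes (1.0, 0.0): lhs ~ 0.707 > 0.3, must be infeasible
  ex <- flux_constraints(fixed = c(R_upt = 10, R_pyk = 10, R_alt = 0))
  f <- solve_fba(fix$model, "R_bio", "max", gr = gr, extra = ex)
  expect_equal(f$status, "infeasible")
  # a symmetric split (0.5, 0.5) is feasible
  ex_ok <- flux_constraints(fixed = c(R_upt = 10, R_pyk = 5, R_alt = 5))
  f_ok <- solve_fba(fix$model, "R_bio", "max", gr = gr, extra = ex_ok)
  expect_equal(f_ok$status, "optimal")
})

test_that("adding GR constraints never widens a flux range", {
  fix <- glyco()
  m <- fix$model
  gr <- glyco_gr(fix)
  ex <- step_constraints(m, "R_exprod", p = 8, z_opt = 6)
  for (rid in m$reactions$id[!m$reactions$exchange]) {
    plain <- flux_range(m, rid, extra = ex)
    con <- flux_range(m, rid, gr = gr, extra = ex)
    expect_gte(con$v_min, plain$v_min - 1e-6)
    expect_lte(con$v_max, plain$v_max + 1e-6)
  }
})

test_that("a scope filter restricts the couplings to the named neighbourhood", {
  fix <- glyco()
  gr <- suppressWarnings(
    build_gr_constraints(fix$model, fix$groups, "glc",
                         scope = c("R_pyk", "R_alt")))
  expect_equal(length(gr$on_off), 1L)
  expect_setequal(gr$on_off[[1]]$members, c("R_pyk", "R_alt"))
  expect_equal(nrow(gr$scale), 1L)
})
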