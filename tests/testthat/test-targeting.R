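test_that("flux bias and flux capacity follow their defining arithmetic", {
  r <- compute_vavg_lsol(v_max = 4, v_min = 2)
  expect_identical(r$v_avg, 3)
  expect_identical(r$l_sol, 2)
  # pinned flux: zero capacity
  r2 <- compute_vavg_lsol(v_max = 7, v_min = 7)
  expect_identical(r2$v_avg, 7)
  expect_identical(r2$l_sol, 0)
  # reversible range straddling zero
  r3 <- compute_vavg_lsol(v_max = 1, v_min = -1)
  expect_identical(r3$v_avg, 0)
  expect_identical(r3$l_sol, 2)
})

test_that("q_slope is the least-squares slope against the enforced flux", {
  expect_equal(compute_qslope(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(compute_qslope(rep(5, 4), c(0, 1, 2, 3)), 0)
  # hand OLS: Sxy = 4, Sxx = 5
  expect_equal(compute_qslope(c(0, 2, 1, 3), c(0, 1, 2, 3)), 0.8)
  expect_warning(out <- compute_qslope(c(0, 1), c(2, 2)), "degenerate")
  expect_true(is.na(out))
  # cross-check against R's reference least-squares fit on random series
  set.seed(42)
  for (i in 1:20) {
    x <- sort(runif(8, 0, 10)); y <- rnorm(8)
    expect_equal(compute_qslope(y, x), unname(coef(lm(y ~ x))[2]),
                 tolerance = 1e-10)
  }
})

test_that("pattern types follow the 3x3 grid of bias and capacity trends", {
  x <- 0:4
  up <- x; down <- -x; flat <- rep(1, 5)
  # rising bias: types 1-3, ordered by capacity trend (down/flat/up)
  expect_equal(classify_pattern(up, down + 10, x), 1L)
  expect_equal(classify_pattern(up, flat, x), 2L)
  expect_equal(classify_pattern(up, up, x), 3L)
  # falling bias: types 4-6
  expect_equal(classify_pattern(down, down + 10, x), 4L)
  expect_equal(classify_pattern(down, flat, x), 5L)
  expect_equal(classify_pattern(down, up, x), 6L)
  # flat or non-monotone bias: types 7-9 (oscillations land here)
  expect_equal(classify_pattern(flat, down + 10, x), 7L)
  expect_equal(classify_pattern(rep(0, 5), flat, x), 8L)
  expect_equal(classify_pattern(c(0, 1, 0, 1, 0), up, x), 9L)
})

test_that("strength partitions monotone from locally dipping candidates", {
  x <- c(0, 1, 2, 3)
  expect_equal(partition_strength(c(0, 1, 2, 3), x), "strong")
  expect_equal(partition_strength(c(0, 2, 1, 3), x), "weak")
  expect_equal(partition_strength(c(3, 2, 1, 0), x), "none")
})

test_that("classification is invariant under uniform flux rescaling", {
  fix <- glyco()
  res1 <- identify_targets(fix$model, fix$groups, scan_config("R_exprod"),
                           carbon_source = "glc")
  c1 <- res1$candidates[order(res1$candidates$reaction_id), ]
  # multiply the uptake rate and every bound by 10
  fix10 <- make_toy_model("glycolysis_like", uptake_cap = 100)
  fix10$model$reactions$upper <- fix10$model$reactions$upper * 10
  cfg10 <- scan_config("R_exprod", uptake_rate = 100)
  res10 <- identify_targets(fix10$model, fix10$groups, cfg10,
                            carbon_source = "glc")
  c10 <- res10$candidates[order(res10$candidates$reaction_id), ]
  expect_equal(c1$reaction_id, c10$reaction_id)
  expect_equal(c1$type, c10$type)
  expect_equal(c1$strength, c10$strength)
  expect_equal(res1$ranked$reaction_id, res10$ranked$reaction_id)
  # slopes are dimensionless flux-per-enforced-flux: unchanged by scaling
  expect_equal(c1$q_slope, c10$q_slope, tolerance = 1e-6)
})

test_that("the product-coupled reaction carries unit slope and tops the ranking", {
  fix <- glyco()
  res <- identify_targets(fix$model, fix$groups, scan_config("R_exprod"),
                          carbon_source = "glc")
  cand <- res$candidates
  prod <- cand[cand$reaction_id == "R_prod", ]
  # 1:1 stoichiometric coupling to the product
  expect_equal(prod$q_slope, 1, tolerance = 1e-6)
  expect_true(prod$type %in% 1:3)
  expect_equal(prod$strength, "strong")
  expect_equal(res$ranked$reaction_id[1], "R_prod")
  # pinned pathway reactions classify flat, the biomass drain negative
  expect_equal(cand$type[cand$reaction_id == "R_gap"], 8L)
  expect_true(cand$type[cand$reaction_id == "R_bio"] %in% 4:6)
  # biomass and target never appear in the ranking
  expect_false(any(c("R_bio", "R_exprod") %in% res$ranked$reaction_id))
})

test_that("ranking prefers strong, then small capacity, then steep slope, then id", {
  base <- data.frame(genes = "", type = 1L, direction = "forward")
  cand <- rbind(
    cbind(base, reaction_id = "R_big", strength = "strong", q_slope = 1,
          mean_v_avg = 1, mean_l_sol = 5.0),
    cbind(base, reaction_id = "R_small", strength = "strong", q_slope = 0.5,
          mean_v_avg = 1, mean_l_sol = 0.1),
    cbind(base, reaction_id = "R_weak", strength = "weak", q_slope = 2,
          mean_v_avg = 1, mean_l_sol = 0.01),
    cbind(base, reaction_id = "R_b", strength = "strong", q_slope = 1,
          mean_v_avg = 1, mean_l_sol = 5.0),
    cbind(base, reaction_id = "R_drop", strength = "n/a", q_slope = 0,
          mean_v_avg = 1, mean_l_sol = 0))
  cand$type[cand$reaction_id == "R_drop"] <- 8L
  ranked <- rank_targets(cand)
  expect_equal(ranked$reaction_id, c("R_small", "R_b", "R_big", "R_weak"))
  expect_equal(ranked$rank, 1:4)
})

test_that("reverse-direction carriers are flagged and still rank as candidates", {
  # a reversible reaction whose flux grows more negative with the product:
  # amplification of its reverse direction
  fix <- glyco()
  scan <- run_scan(fix$model, NULL, scan_config("R_exprod"))
  flipped <- scan
  for (i in seq_along(flipped$steps)) {
    r <- flipped$steps[[i]]$ranges
    sel <- r$reaction_id == "R_prod"
    vmin <- r$v_min[sel]; vmax <- r$v_max[sel]
    r$v_min[sel] <- -vmax; r$v_max[sel] <- -vmin
    flipped$steps[[i]]$ranges <- r
  }
  cand <- evaluate_targets(flipped, fix$model)
  prod <- cand[cand$reaction_id == "R_prod", ]
  expect_equal(prod$direction, "reverse")
  expect_true(prod$type %in% 1:3)
  expect_equal(prod$q_slope, 1, tolerance = 1e-6)
})
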