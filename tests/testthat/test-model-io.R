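test_that("model construction assembles the stoichiometric matrix and applies bound defaults", {
  mets <- data.frame(id = c("X", "A", "B"), boundary = c(TRUE, FALSE, FALSE))
  rx <- data.frame(id = c("R1", "R2"), reversible = c(FALSE, TRUE))
  sto <- list(R1 = c(X = -1, A = 1), R2 = c(A = -1, B = 1))
  m <- metabolic_model(mets, rx, sto)
  expect_equal(dim(m$S), c(3L, 2L))
  expect_equal(nrow(m$metabolites), 3L)
  expect_equal(nrow(m$reactions), 2L)
  expect_equal(as.numeric(m$S["A", ]), c(1, -1))
  # irreversible default [0, 1000], reversible default [-1000, 1000]
  expect_equal(m$reactions$lower, c(0, -1000))
  expect_equal(m$reactions$upper, c(1000, 1000))
})

test_that("model validation rejects inconsistent inputs", {
  mets <- data.frame(id = c("A", "B"))
  expect_error(
    metabolic_model(mets, data.frame(id = "R1"), list(R1 = c(A = -1, Z = 1))),
    "unknown metabolite")
  expect_error(
    metabolic_model(mets, data.frame(id = "R1", lower = 5, upper = 1),
                    list(R1 = c(A = -1, B = 1))),
    "lower bound exceeds")
  expect_error(
    metabolic_model(mets, data.frame(id = "R1", lower = -1, upper = 1,
                                     reversible = FALSE),
                    list(R1 = c(A = -1, B = 1))),
    "irreversible")
  expect_error(
    metabolic_model(mets, data.frame(id = "R1"),
                    list(R1 = c(A = -1, B = 1)), biomass = "nope"),
    "biomass_id")
})

test_that("carbon counting parses formulas and rejects residues", {
  expect_equal(count_carbons(c("C6H12O6", "C3H7O6P", "H2O", "CoCl2")),
               c(6L, 3L, 0L, 0L))
  # two-letter elements are not carbon; multi-digit counts parse
  expect_equal(count_carbons("C10H16N5O13P3"), 10L)
  expect_true(is.na(count_carbons("C5H8NO4R")))
  expect_true(is.na(count_carbons(NA_character_)))
  expect_true(is.na(count_carbons("(C6H10O5)n")))
})

test_that("SBML round-trip preserves stoichiometry, bounds and formulas exactly", {
  fix <- make_toy_model("glycolysis_like")
  path <- tempfile(fileext = ".xml")
  write_sbml(fix$model, path)
  back <- read_sbml(path, uptake = "R_upt")
  expect_equal(back$metabolites$id, fix$model$metabolites$id)
  expect_equal(back$metabolites$formula, fix$model$metabolites$formula)
  expect_equal(back$metabolites$boundary, fix$model$metabolites$boundary)
  expect_identical(as.matrix(back$S), as.matrix(fix$model$S))
  expect_identical(back$reactions$lower, fix$model$reactions$lower)
  expect_identical(back$reactions$upper, fix$model$reactions$upper)
  expect_equal(back$biomass_id, "R_bio")  # via the fbc objective
  # gene annotations survive the notes round trip
  expect_equal(back$reactions$genes[back$reactions$id == "R_pgi"], "glk")
})

test_that("legacy level-2 SBML with kinetic-law bounds and notes formulas is read", {
  path <- tempfile(fileext = ".xml")
  writeLines(legacy_sbml_text(), path)
  m <- read_sbml(path, biomass = "R_conv")
  expect_equal(nrow(m$metabolites), 3L)
  expect_equal(nrow(m$reactions), 2L)
  expect_equal(m$reactions$upper[m$reactions$id == "R_in"], 12.5)
  expect_equal(m$reactions$lower[m$reactions$id == "R_in"], 0)
  # missing bounds default to [0, 1000] for an irreversible reaction
  expect_equal(m$reactions$lower[m$reactions$id == "R_conv"], 0)
  expect_equal(m$reactions$upper[m$reactions$id == "R_conv"], 1000)
  expect_equal(m$metabolites$formula[m$metabolites$id == "A"], "C3H4O3")
  expect_true(m$metabolites$boundary[m$metabolites$id == "S_ext"])
  expect_true(m$reactions$exchange[m$reactions$id == "R_in"])
  expect_setequal(strsplit(m$reactions$genes[2], ";")[[1]],
                  c("gA", "gB", "gC"))
})

test_that("unparseable SBML and unknown species are fatal", {
  bad <- tempfile(fileext = ".xml")
  writeLines("this is not xml <", bad)
  expect_error(read_sbml(bad), "unparseable")
})

test_that("group files parse, validate ids, and drop singletons", {
  fix <- make_toy_model("glycolysis_like")
  path <- tempfile(fileext = ".tsv")
  writeLines(c("G1\tR_fba\tneighborhood", "G1\tR_tpi\tneighborhood"), path)
  g <- read_groups(path, fix$model)
  expect_equal(group_members(g), list(G1 = c("R_fba", "R_tpi")))

  writeLines(c("G1\tR_fba\tneighborhood", "G1\tR_nope\tneighborhood"), path)
  expect_error(read_groups(path, fix$model), "line 2.*R_nope")

  writeLines(c("group_id\treaction_id\tevidence",
               "G1\tR_fba\tneighborhood", "G1\tR_tpi\tneighborhood",
               "G2\tR_pyk\tmanual"), path)
  expect_warning(g2 <- read_groups(path, fix$model), "fewer than 2")
  expect_equal(names(group_members(g2)), "G1")
})

test_that("target reports round-trip with deterministic tie-broken ordering", {
  empty <- data.frame(reaction_id = character(0), genes = character(0),
                      type = integer(0), strength = character(0),
                      direction = character(0), q_slope = numeric(0),
                      mean_v_avg = numeric(0), mean_l_sol = numeric(0),
                      rank = integer(0))
  path <- tempfile(fileext = ".tsv")
  write_target_report(empty, path)
  expect_equal(readLines(path),
               "reaction_id\tgenes\ttype\tstrength\tdirection\tq_slope\tmean_v_avg\tmean_l_sol\trank")

  two <- data.frame(reaction_id = c("R_z", "R_a"), genes = c("gz", "ga"),
                    type = c(1L, 1L), strength = "strong",
                    direction = "forward", q_slope = c(1, 1),
                    mean_v_avg = c(2, 2), mean_l_sol = c(0, 0),
                    rank = c(1L, 1L))
  write_target_report(two, path)
  back <- read_target_report(path)
  expect_equal(back$reaction_id, c("R_a", "R_z"))  # lexicographic tie-break

  # full round trip from a real scan
  fix <- glyco()
  res <- identify_targets(fix$model, fix$groups, scan_config("R_exprod"),
                          carbon_source = "glc")
  write_target_report(res$ranked, path)
  back <- read_target_report(path)
  expect_equal(back$reaction_id, res$ranked$reaction_id)
  expect_equal(back$q_slope, res$ranked$q_slope, tolerance = 1e-9)
  expect_equal(back$rank, res$ranked$rank)
  expect_equal(back$type, res$ranked$type)
})
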