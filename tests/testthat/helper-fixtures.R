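# Shared fixture helpers.  All fixtures are generated in code; the analytic
# expectations (yields, growth line, scale band) are hand mass balances on
# the glycolysis-like toy network: uptake 10 of a C6 source splits into 20 C3
# units; biomass consumes one PEP + one pyruvate, the product drains
# pyruvate, overflow secretes pyruvate, so optimal growth at enforced
# product flux p is (20 - p)/2.

glyco <- function(seed = NULL) make_toy_model("glycolysis_like", seed = seed)

glyco_gr <- function(fix) build_gr_constraints(fix$model, fix$groups, "glc")

# scale band half-width for delta = 0.3, uptake 10
scale_band <- function(delta = 0.3, uptake = 10) delta * sqrt(2) * uptake

# total pyruvate-kinase flux at enforced product flux p, growth at 95%
pyk_total <- function(p, frac = 0.95) 20 - frac * (20 - p) / 2

expect_range_equal <- function(got, v_min, v_max, tol = 1e-5) {
  expect_equal(got$status_min, "optimal")
  expect_equal(got$status_max, "optimal")
  expect_equal(got$v_min, v_min, tolerance = tol)
  expect_equal(got$v_max, v_max, tolerance = tol)
}

# compare solver flux range with the brute-force oracle
expect_matches_oracle <- function(model, rid, gr = NULL, extra = NULL,
                                  tol = 1e-5) {
  a <- flux_range(model, rid, gr = gr, extra = extra)
  b <- brute_force_fva_oracle(model, rid, gr = gr, extra = extra)
  expect_equal(a$status_min, b$status_min)
  expect_equal(a$status_max, b$status_max)
  if (a$status_min == "optimal") {
    expect_equal(a$v_min, b$v_min, tolerance = tol)
    expect_equal(a$v_max, b$v_max, tolerance = tol)
  }
  invisible(list(solver = a, oracle = b))
}

# constraints used at one scan step
step_constraints <- function(model, target, p, z_opt, frac = 0.95,
                             uptake = 10) {
  flux_constraints(fixed = stats::setNames(
    c(uptake, p, frac * z_opt),
    c(model$uptake_id, target, model$biomass_id)))
}

# legacy SBML level 2 text with kinetic-law bounds, notes formulas and a
# GENE_ASSOCIATION annotation, for reader coverage
legacy_sbml_text <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">\n',
    '<model id="legacy">\n',
    '<listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>\n',
    '<listOfSpecies>\n',
    '<species id="S_ext" compartment="e" boundaryCondition="true"/>\n',
    '<species id="A" compartment="c">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>FORMULA: C3H4O3</p></body></notes>',
    '</species>\n',
    '<species id="B" compartment="c">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>FORMULA: C3H6O3</p></body></notes>',
    '</species>\n',
    '</listOfSpecies>\n',
    '<listOfReactions>\n',
    '<reaction id="R_in" reversible="false">\n',
    '<listOfReactants><speciesReference species="S_ext"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="A"/></listOfProducts>\n',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"/>',
    '<listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="12.5"/>',
    '</listOfParameters></kineticLaw>\n',
    '</reaction>\n',
    '<reaction id="R_conv" reversible="false">\n',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (gA and gB) or gC</p></body></notes>\n',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>\n',
    '</reaction>\n',
    '</listOfReactions>\n',
    '</model>\n</sbml>\n')
}
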