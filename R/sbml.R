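#' Read a metabolic model from SBML
#'
#' Supports the two bound conventions found in BiGG-era genome-scale models:
#' SBML Level 3 with the fbc (v2) package, where bounds are parameters
#' referenced from `fbc:lowerFluxBound`/`fbc:upperFluxBound`, and legacy
#' Level 2 files where bounds live in per-reaction kinetic-law parameters
#' named `LOWER_BOUND`/`UPPER_BOUND`.  When both are present, fbc wins.
#' Missing bounds default to -1000/1000 (reversible) or 0/1000
#' (irreversible) mmol/gDCW/h.  Chemical formulas are taken from
#' `fbc:chemicalFormula` or, failing that, a `FORMULA: ...` line in the
#' species notes; species without a formula are kept but flagged with a
#' warning (their reactions are exempt from CxJy indexing).  Species with
#' `boundaryCondition="true"` are exempt from mass balance and flagged
#' extracellular.
#'
#' @param path SBML file path.
#' @param biomass optional biomass reaction id; when `NULL` the active fbc
#'   objective is used, falling back to the first reaction id matching
#'   "biomass" (case-insensitive).
#' @param uptake optional carbon-source uptake reaction id (SBML has no slot
#'   for this; it may also be set later or given in the scan configuration).
#' @param ext_compartments compartment ids treated as extracellular.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path, biomass = NULL, uptake = NULL,
                      ext_compartments = c("e", "e0", "extracellular")) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable SBML file '", path,
                                           "': ", conditionMessage(e)))
  find <- function(node, tag)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", tag))
  attr_any <- function(attrs, name) {
    hit <- which(names(attrs) == name | endsWith(names(attrs), paste0(":", name)))
    if (length(hit) == 0) NA_character_ else unname(attrs[hit[1]])
  }

  ## global parameters (fbc bound style)
  model_node <- find(doc, "model")[[1]]
  params <- c()
  for (p in find(model_node, "parameter")) {
    a <- xml2::xml_attrs(p)
    if (!is.na(attr_any(a, "id")) && !is.na(attr_any(a, "value")))
      params[attr_any(a, "id")] <- as.numeric(attr_any(a, "value"))
  }

  ## species
  sp_nodes <- find(model_node, "species")
  species <- lapply(sp_nodes, function(s) {
    a <- xml2::xml_attrs(s)
    formula <- attr_any(a, "chemicalFormula")
    if (is.na(formula)) {
      notes <- paste(xml2::xml_text(find(s, "notes")), collapse = " ")
      m <- regmatches(notes, regexpr("FORMULA:\\s*\\S+", notes))
      if (length(m) == 1) formula <- sub("FORMULA:\\s*", "", m)
    }
    boundary <- identical(attr_any(a, "boundaryCondition"), "true")
    comp <- attr_any(a, "compartment")
    data.frame(id = attr_any(a, "id"), formula = formula,
               compartment = ifelse(is.na(comp), "c", comp),
               extracellular = boundary || (!is.na(comp) && comp %in% ext_compartments),
               boundary = boundary, lower = 0, upper = 0)
  })
  metabolites <- do.call(rbind, species)
  n_noformula <- sum(is.na(metabolites$formula) & !metabolites$boundary)
  if (n_noformula > 0)
    warning(n_noformula, " species without a chemical formula; their ",
            "reactions will be excluded from CxJy indexing")

  ## reactions
  rx_nodes <- find(model_node, "reaction")
  sto <- list()
  rows <- lapply(rx_nodes, function(r) {
    a <- xml2::xml_attrs(r)
    id <- attr_any(a, "id")
    rev_attr <- attr_any(a, "reversible")
    reversible <- is.na(rev_attr) || identical(rev_attr, "true")
    coefs <- c()
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      for (ln in find(r, side)) {
        for (sr in find(ln, "speciesReference")) {
          sa <- xml2::xml_attrs(sr)
          st <- attr_any(sa, "stoichiometry")
          st <- if (is.na(st)) 1 else as.numeric(st)
          spid <- attr_any(sa, "species")
          coefs[spid] <- (if (spid %in% names(coefs)) coefs[spid] else 0) + sign * st
        }
      }
    }
    unknown <- setdiff(names(coefs), metabolites$id)
    if (length(unknown) > 0)
      stop("reaction '", id, "' references unknown species: ",
           paste(unknown, collapse = ", "))
    sto[[id]] <<- coefs

    lb <- ub <- NA_real_
    lb_ref <- attr_any(a, "lowerFluxBound"); ub_ref <- attr_any(a, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(params)) lb <- params[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(params)) ub <- params[[ub_ref]]
    if (is.na(lb) || is.na(ub)) {  # legacy kinetic-law bounds
      for (kp in find(r, "localParameter")) {
        ka <- xml2::xml_attrs(kp)
        nm <- attr_any(ka, "id"); if (is.na(nm)) nm <- attr_any(ka, "name")
        if (identical(nm, "LOWER_BOUND") && is.na(lb)) lb <- as.numeric(attr_any(ka, "value"))
        if (identical(nm, "UPPER_BOUND") && is.na(ub)) ub <- as.numeric(attr_any(ka, "value"))
      }
      for (kl in find(r, "kineticLaw")) {
        for (kp in find(kl, "parameter")) {
          ka <- xml2::xml_attrs(kp)
          nm <- attr_any(ka, "id"); if (is.na(nm)) nm <- attr_any(ka, "name")
          if (identical(nm, "LOWER_BOUND") && is.na(lb)) lb <- as.numeric(attr_any(ka, "value"))
          if (identical(nm, "UPPER_BOUND") && is.na(ub)) ub <- as.numeric(attr_any(ka, "value"))
        }
      }
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000

    notes <- paste(xml2::xml_text(find(r, "notes")), collapse = " ")
    genes <- ""
    gm <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
    if (length(gm) == 1) {
      g <- sub("GENE_ASSOCIATION:\\s*", "", gm)
      g <- gsub("[()]", " ", g)
      g <- unlist(strsplit(g, "\\s+(and|or)\\s+|\\s+"))
      genes <- paste(unique(g[nzchar(g) & !g %in% c("and", "or")]), collapse = ";")
    }
    boundary_touch <- any(names(coefs) %in% metabolites$id[metabolites$boundary])
    one_sided <- all(coefs < 0) || all(coefs > 0)
    data.frame(id = id, lower = lb, upper = ub, reversible = reversible,
               exchange = boundary_touch || one_sided || grepl("^(R_)?EX_", id),
               genes = genes)
  })
  reactions <- do.call(rbind, rows)

  if (is.null(biomass)) {
    fo <- find(model_node, "fluxObjective")
    if (length(fo) > 0) {
      a <- xml2::xml_attrs(fo[[1]])
      biomass <- attr_any(a, "reaction")
    } else {
      hit <- grep("biomass", reactions$id, ignore.case = TRUE, value = TRUE)
      biomass <- if (length(hit) > 0) hit[1] else NA_character_
    }
  }
  metabolic_model(metabolites, reactions, sto,
                  biomass = biomass %||% NA_character_,
                  uptake = uptake %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a metabolic model as SBML Level 3 with fbc v2 bounds
#'
#' Emits species (with `boundaryCondition` and `fbc:chemicalFormula`),
#' per-reaction bound parameters, stoichiometry, the biomass reaction as the
#' active fbc objective, and gene annotations as legacy
#' `GENE_ASSOCIATION` notes.  A model written here and re-read with
#' [read_sbml()] preserves stoichiometry, bounds and formulas exactly.
#' Net-transport bounds of extracellular species are not serialised (they
#' default to zero on read); exchange with the environment should be encoded
#' as explicit exchange reactions against boundary species.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  m <- model$metabolites; r <- model$reactions
  num <- function(x) sprintf("%.17g", x)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="false">',
    '    <listOfCompartments>')
  for (comp in unique(m$compartment))
    out <- c(out, sprintf('      <compartment id="%s" constant="true"/>',
                          .xml_escape(comp)))
  out <- c(out, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(m))) {
    formula_attr <- if (!is.na(m$formula[i]) && nzchar(m$formula[i]))
      sprintf(' fbc:chemicalFormula="%s"', .xml_escape(m$formula[i])) else ""
    out <- c(out, sprintf(
      paste0('      <species id="%s" compartment="%s" boundaryCondition="%s" ',
             'hasOnlySubstanceUnits="false" constant="false"%s/>'),
      .xml_escape(m$id[i]), .xml_escape(m$compartment[i]),
      tolower(as.character(m$boundary[i])), formula_attr))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(r)))
    out <- c(out,
             sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>',
                     .xml_escape(r$id[i]), num(r$lower[i])),
             sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
                     .xml_escape(r$id[i]), num(r$upper[i])))
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(r))) {
    rid <- r$id[i]
    sto <- model$S[, rid]
    sto <- sto[sto != 0]
    out <- c(out, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">'),
      .xml_escape(rid), tolower(as.character(r$reversible[i])),
      .xml_escape(rid), .xml_escape(rid)))
    if (nzchar(r$genes[i]))
      out <- c(out,
               '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
               sprintf('          <p>GENE_ASSOCIATION: %s</p>',
                       .xml_escape(gsub(";", " or ", r$genes[i]))),
               '        </body></notes>')
    subs <- sto[sto < 0]; prods <- sto[sto > 0]
    if (length(subs) > 0) {
      out <- c(out, '        <listOfReactants>')
      for (k in seq_along(subs))
        out <- c(out, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          .xml_escape(names(subs)[k]), num(-subs[k])))
      out <- c(out, '        </listOfReactants>')
    }
    if (length(prods) > 0) {
      out <- c(out, '        <listOfProducts>')
      for (k in seq_along(prods))
        out <- c(out, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          .xml_escape(names(prods)[k]), num(prods[k])))
      out <- c(out, '        </listOfProducts>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  if (!is.na(model$biomass_id))
    out <- c(out,
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>',
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     .xml_escape(model$biomass_id)),
             '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>')
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}
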