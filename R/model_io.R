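#' Construct a stoichiometric metabolic model
#'
#' The central container used by every other function in the package: a list
#' of metabolites, a list of reactions, and the sparse stoichiometric matrix
#' assembled from per-reaction stoichiometries.  Steady-state mass balance is
#' expressed as `S v = b`, where `b` is zero for every intermediate and, for
#' extracellular metabolites, is bounded by their net-transport bounds.
#'
#' @param metabolites data.frame with columns `id` (unique identifiers) and
#'   optionally `formula` (elemental formula string, e.g. `"C6H12O6"`; `NA`
#'   when unknown), `compartment`, `extracellular` (logical),
#'   `boundary` (logical; boundary species are exempt from mass balance),
#'   `lower`/`upper` (net transport bounds, mmol/gDCW/h, extracellular only;
#'   default both 0).
#' @param reactions data.frame with columns `id` and optionally `lower`,
#'   `upper` (flux bounds; defaults -1000/1000 for reversible and 0/1000 for
#'   irreversible reactions), `reversible` (logical; default inferred as
#'   `lower < 0`), `exchange` (logical; default `FALSE`), `genes`
#'   (semicolon-separated gene symbols, annotation only).
#' @param stoichiometry named list, one element per reaction id, each a named
#'   numeric vector of stoichiometric coefficients (negative = consumed).
#' @param biomass id of the biomass pseudo-reaction (growth objective).
#' @param uptake id of the carbon-source uptake reaction.
#'
#' @return An object of class `metabolic_model` with elements `metabolites`,
#'   `reactions`, `S` (sparse matrix, metabolites x reactions), `biomass_id`,
#'   `uptake_id`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            biomass = NA_character_, uptake = NA_character_) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(is.list(stoichiometry))

  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$extracellular)) metabolites$extracellular <- FALSE
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  if (is.null(metabolites$lower)) metabolites$lower <- 0
  if (is.null(metabolites$upper)) metabolites$upper <- 0

  if (is.null(reactions$reversible)) {
    reactions$reversible <- if (is.null(reactions$lower)) FALSE else reactions$lower < 0
  }
  if (is.null(reactions$lower)) reactions$lower <- ifelse(reactions$reversible, -1000, 0)
  if (is.null(reactions$upper)) reactions$upper <- 1000
  if (is.null(reactions$exchange)) reactions$exchange <- FALSE
  if (is.null(reactions$genes)) reactions$genes <- ""
  reactions$genes[is.na(reactions$genes)] <- ""

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         S = .assemble_stoichiometry(metabolites$id, reactions$id, stoichiometry),
         biomass_id = biomass, uptake_id = uptake),
    class = "metabolic_model")
  validate_model(model)
  model
}

.assemble_stoichiometry <- function(met_ids, rxn_ids, stoichiometry) {
  missing <- setdiff(rxn_ids, names(stoichiometry))
  if (length(missing) > 0)
    stop("no stoichiometry given for reaction(s): ", paste(missing, collapse = ", "))
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (jj in seq_along(rxn_ids)) {
    sto <- stoichiometry[[rxn_ids[jj]]]
    if (length(sto) == 0) next
    unknown <- setdiff(names(sto), met_ids)
    if (length(unknown) > 0)
      stop("reaction ", rxn_ids[jj], " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    i <- c(i, match(names(sto), met_ids))
    j <- c(j, rep(jj, length(sto)))
    x <- c(x, unname(sto))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Validate the internal consistency of a metabolic model
#'
#' Checks identifier uniqueness, bound ordering (`lower <= upper`,
#' non-negative lower bounds for irreversible reactions), matrix dimensions,
#' and that the biomass/uptake reaction ids resolve when set.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  m <- model$metabolites; r <- model$reactions
  if (anyDuplicated(m$id)) stop("duplicated metabolite ids")
  if (anyDuplicated(r$id)) stop("duplicated reaction ids")
  if (any(r$lower > r$upper)) {
    bad <- r$id[r$lower > r$upper]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  if (any(!r$reversible & r$lower < 0)) {
    bad <- r$id[!r$reversible & r$lower < 0]
    stop("irreversible reaction with negative lower bound: ",
         paste(bad, collapse = ", "))
  }
  if (!identical(dim(model$S), c(nrow(m), nrow(r))))
    stop("stoichiometric matrix dimensions do not match metabolite/reaction counts")
  for (field in c("biomass_id", "uptake_id")) {
    id <- model[[field]]
    if (!is.na(id) && !id %in% r$id)
      stop(field, " '", id, "' is not a reaction in the model")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions\n")
  cat("  biomass:", x$biomass_id, " uptake:", x$uptake_id, "\n")
  invisible(x)
}

#' Count carbon atoms in an elemental formula
#'
#' Parses element symbols with optional counts (e.g. `"C6H12O6"` gives 6).
#' Two-letter elements are recognised, so chlorine or cobalt are never
#' miscounted as carbon.  Formulas that are missing, contain residue/R-group
#' placeholders, or do not tokenise cleanly yield `NA`, which marks the
#' metabolite's reactions as exempt from CxJy indexing downstream.
#'
#' @param formula character vector of formula strings.
#' @return integer vector of carbon counts (`NA` where unparseable).
#' @export
count_carbons <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_integer_)
    tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    matched <- sum(attr(tokens, "match.length"))
    if (matched != nchar(f)) return(NA_integer_)  # residues, parentheses, '*'
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    elements <- sub("[0-9]*$", "", parts)
    if (any(elements %in% c("R", "X"))) return(NA_integer_)
    counts <- as.integer(sub("^[A-Za-z]+", "", parts))
    counts[is.na(counts)] <- 1L
    sum(counts[elements == "C"])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a tab-separated reaction-group file
#'
#' Groups of functionally coupled reactions, one row per (group, member)
#' pair, as produced by genomic-context analysis (conserved neighbourhood,
#' gene fusion, co-occurrence).  Columns: `group_id`, `reaction_id`,
#' `evidence`; a header row is tolerated but not required, and a missing
#' evidence column defaults to `"manual"`.
#'
#' @param path path to the TSV file.
#' @param model `metabolic_model` the member ids must resolve against.
#' @return A `reaction_groups` object: a data.frame of (group_id,
#'   reaction_id, evidence) rows.  Groups with fewer than two members are
#'   dropped with a warning.
#' @export
read_groups <- function(path, model) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(reaction_groups(data.frame(group_id = character(0),
                                      reaction_id = character(0),
                                      evidence = character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]]))
  has_header <- identical(first[1], "group_id")
  if (has_header) { lines <- lines[-1]; fields <- fields[-1] }
  rows <- lapply(seq_along(fields), function(ln) {
    f <- trimws(fields[[ln]])
    if (length(f) < 2)
      stop("groups file line ", ln + has_header, ": expected at least 2 fields")
    data.frame(group_id = f[1], reaction_id = f[2],
               evidence = if (length(f) >= 3 && nzchar(f[3])) f[3] else "manual",
               line = ln + has_header)
  })
  df <- do.call(rbind, rows)
  bad <- !df$reaction_id %in% model$reactions$id
  if (any(bad)) {
    k <- which(bad)[1]
    stop("groups file line ", df$line[k], ": unknown reaction id '",
         df$reaction_id[k], "'")
  }
  reaction_groups(df[, c("group_id", "reaction_id", "evidence")])
}

#' Construct a reaction-group set
#'
#' @param df data.frame with columns `group_id`, `reaction_id` and optionally
#'   `evidence` (one of neighborhood, fusion, cooccurrence, manual).
#' @return A `reaction_groups` object.  Singleton groups (after removing
#'   duplicate members) are dropped with a warning.
#' @export
reaction_groups <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$evidence)) df$evidence <- "manual"
  known <- c("neighborhood", "fusion", "cooccurrence", "manual")
  if (any(!df$evidence %in% known))
    warning("unrecognised evidence tag(s): ",
            paste(unique(setdiff(df$evidence, known)), collapse = ", "))
  df <- df[!duplicated(df[, c("group_id", "reaction_id")]), , drop = FALSE]
  sizes <- table(df$group_id)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    warning("dropping group(s) with fewer than 2 members: ",
            paste(singletons, collapse = ", "))
    df <- df[!df$group_id %in% singletons, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("reaction_groups", "data.frame"))
}

#' Split a reaction-group set into a per-group list of member ids
#'
#' @param groups a `reaction_groups` object.
#' @return Named list of character vectors of member reaction ids.
#' @export
group_members <- function(groups) {
  if (nrow(groups) == 0) return(list())
  split(groups$reaction_id, groups$group_id)
}

#' Write a groups table to a TSV file
#'
#' @param groups a `reaction_groups` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(as.data.frame(groups)[, c("group_id", "reaction_id", "evidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.report_columns <- c("reaction_id", "genes", "type", "strength", "direction",
                     "q_slope", "mean_v_avg", "mean_l_sol", "rank")

#' Write a ranked amplification-target report
#'
#' One row per candidate, ordered by rank and then reaction id (the
#' deterministic tie-break).  `strength` is `"n/a"` for candidates outside
#' the positively correlated pattern types.
#'
#' @param candidates data.frame as returned by [rank_targets()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_report <- function(candidates, path) {
  df <- as.data.frame(candidates, stringsAsFactors = FALSE)
  for (col in .report_columns)
    if (is.null(df[[col]])) df[[col]] <- if (col %in% c("reaction_id", "genes", "strength", "direction")) character(0) else numeric(0)
  df <- df[, .report_columns, drop = FALSE]
  if (nrow(df) > 0) {
    df$strength[is.na(df$strength)] <- "n/a"
    df <- df[order(df$rank, df$reaction_id), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a target report written by [write_target_report()]
#'
#' @param path TSV path.
#' @return data.frame with the report columns.
#' @export
read_target_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(reaction_id = "character",
                                         genes = "character",
                                         strength = "character",
                                         direction = "character"))
  df$genes[is.na(df$genes)] <- ""
  df
}
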