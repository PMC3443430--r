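## Grouping-reaction (GR) constraints.  Functionally coupled reactions
## (genomic-context groups) are tied two ways: a shared on/off binary with
## activation bounds y*alpha_j <= v_j <= y*beta_j, and, for group pairs whose
## flux-converging CxJy indices agree, a flux-scale coupling that keeps the
## two uptake-normalised fluxes within delta of their common midpoint.

#' Default cofactor metabolite ids
#'
#' Cofactors are excluded from carbon counting and from the metabolite
#' digraph: flux scale is controlled by the carbon of primary metabolites.
#' Matching is case-insensitive on the id with a trailing compartment suffix
#' (`_c`, `[c]`, ...) stripped.
#'
#' @return character vector of cofactor base ids.
#' @export
default_cofactors <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "coa", "accoa",
    "pi", "ppi", "h", "h2o", "co2", "o2", "nh4", "fad", "fadh2", "gtp",
    "gdp", "utp", "udp")
}

#' Read a cofactor list from a plain-text file (one metabolite id per line)
#'
#' @param path file path; blank lines and `#` comments are ignored.
#' @return character vector of ids.
#' @export
read_cofactors <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

.strip_compartment <- function(id)
  tolower(sub("(_[a-z][0-9]?|\\[[a-z]\\])$", "", id))

.is_cofactor <- function(ids, cofactors)
  .strip_compartment(ids) %in% .strip_compartment(cofactors)

## Directed metabolite graph: one edge per (primary substrate, primary
## product) pair of each reaction; reversible reactions contribute both
## directions.  Cofactors and boundary species are excluded.
.metabolite_graph <- function(model, cofactors = default_cofactors()) {
  met <- model$metabolites
  keep <- met$id[!met$boundary & !.is_cofactor(met$id, cofactors)]
  edges <- character(0)
  for (j in seq_len(nrow(model$reactions))) {
    sto <- model$S[, j]
    subs <- intersect(names(sto)[sto < 0], keep)
    prods <- intersect(names(sto)[sto > 0], keep)
    if (length(subs) == 0 || length(prods) == 0) next
    for (s in subs) for (p in prods) {
      edges <- c(edges, s, p)
      if (model$reactions$reversible[j]) edges <- c(edges, p, s)
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(keep)
  if (length(edges) > 0) g <- igraph::add_edges(g, match(edges, keep))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

## Number of internally vertex-disjoint directed s->t paths, via max-flow on
## the standard node-split transform (so it stays correct when s and t are
## also directly adjacent).
.disjoint_paths <- function(g, s, t) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ## vertex v -> v_in = v, v_out = v + n; internal capacity 1, s/t uncapped
  cap_internal <- rep(1, n)
  cap_internal[c(s, t)] <- n + 1
  edges <- rbind(cbind(seq_len(n), seq_len(n) + n),
                 cbind(el[, 1] + n, el[, 2]))
  caps <- c(cap_internal, rep(n + 1, nrow(el)))
  h <- igraph::make_empty_graph(n = 2 * n, directed = TRUE)
  h <- igraph::add_edges(h, t(edges))
  igraph::max_flow(h, source = s + n, target = t, capacity = caps)$value
}

#' Find flux-converging metabolites
#'
#' A flux-converging metabolite is one at which two pathways, split earlier
#' at another metabolite, recombine: there exist an ancestor metabolite and
#' at least two internally node-disjoint directed routes from that ancestor
#' which rejoin at the metabolite.  Computed on the primary-metabolite
#' digraph (cofactors removed), restricted to metabolites reachable from the
#' carbon source.
#'
#' @param model a [metabolic_model()].
#' @param carbon_source metabolite id of the (intracellular) carbon source.
#' @param cofactors cofactor id list, see [default_cofactors()].
#' @return character vector of metabolite ids (empty, with a warning, when
#'   the carbon source is absent from or unreachable in the graph).
#' @export
find_flux_converging_metabolites <- function(model, carbon_source,
                                             cofactors = default_cofactors()) {
  g <- .metabolite_graph(model, cofactors)
  vn <- igraph::V(g)$name
  if (!carbon_source %in% vn) {
    warning("carbon source '", carbon_source, "' not in the metabolite graph")
    return(character(0))
  }
  src <- match(carbon_source, vn)
  reach <- igraph::subcomponent(g, src, mode = "out")
  reachable <- sort(as.integer(reach))
  if (length(reachable) <= 1) {
    warning("carbon source '", carbon_source, "' reaches no other metabolite")
    return(character(0))
  }
  conv <- character(0)
  for (m in reachable) {
    if (igraph::degree(g, m, mode = "in") < 2) next
    ancestors <- setdiff(as.integer(igraph::subcomponent(g, m, mode = "in")), m)
    ancestors <- intersect(ancestors, reachable)
    for (a in ancestors) {
      if (.disjoint_paths(g, a, m) >= 2) {
        conv <- c(conv, vn[m])
        break
      }
    }
  }
  sort(conv)
}

#' Carbon index of one reaction
#'
#' Sums the carbon atoms of every primary (non-cofactor) participant,
#' substrates and products alike; the half-count `x = N_C/2` is the carbon
#' component of the CxJy index.
#'
#' @param model a [metabolic_model()].
#' @param reaction reaction id.
#' @param cofactors cofactor ids to exclude.
#' @return list with `n_c` (total primary carbon) and `x` (`n_c / 2`); both
#'   `NA` when any primary participant lacks a parseable formula.
#' @export
carbon_index <- function(model, reaction, cofactors = default_cofactors()) {
  sto <- model$S[, reaction]
  ids <- names(sto)[sto != 0]
  ids <- ids[!.is_cofactor(ids, cofactors)]
  carb <- count_carbons(model$metabolites$formula[match(ids, model$metabolites$id)])
  if (length(ids) == 0 || anyNA(carb))
    return(list(n_c = NA_real_, x = NA_real_))
  list(n_c = sum(carb), x = sum(carb) / 2)
}

#' Assign flux-converging CxJy indices to every indexable reaction
#'
#' For each reaction, enumerates the simple directed routes from the carbon
#' source to each of the reaction's primary substrates.  Per route, the tag
#' letter counts the distinct flux-converging metabolites passed *strictly
#' upstream* of the substrate (the substrate itself is not counted):
#' A/B/C/D for 0/1/2/3, counts above 3 clamping to D.  An `E` suffix marks
#' routes derived from pyruvate, i.e. routes on which pyruvate appears
#' (including as the terminal substrate).  The set of distinct `(x, tag)`
#' pairs, slash-joined, is the reaction's index; a pure function of the model
#' digraph.
#'
#' @inheritParams find_flux_converging_metabolites
#' @param pyruvate metabolite id treated as pyruvate; default any id whose
#'   compartment-stripped form is `"pyr"`.
#' @param max_routes cap on enumerated routes per reaction; indexing past the
#'   cap proceeds on the truncated route set with a warning.
#' @return data.frame with one row per reaction: `reaction_id`, `indexable`,
#'   `n_c`, `x`, `entries` (slash-joined, e.g. `"C6JA/C6JB"`).
#' @export
assign_cxjy <- function(model, carbon_source, cofactors = default_cofactors(),
                        pyruvate = NULL, max_routes = 10000) {
  conv <- find_flux_converging_metabolites(model, carbon_source, cofactors)
  g <- .metabolite_graph(model, cofactors)
  vn <- igraph::V(g)$name
  if (is.null(pyruvate)) {
    hit <- vn[.strip_compartment(vn) == "pyr"]
    pyruvate <- if (length(hit) > 0) hit[1] else NA_character_
  }
  src_ok <- carbon_source %in% vn

  path_cache <- new.env(parent = emptyenv())
  routes_to <- function(target) {
    if (!is.null(path_cache[[target]])) return(path_cache[[target]])
    paths <- if (!src_ok || !target %in% vn) {
      list()
    } else if (target == carbon_source) {
      list(carbon_source)
    } else {
      p <- igraph::all_simple_paths(g, from = carbon_source, to = target,
                                    mode = "out")
      lapply(p, function(v) vn[as.integer(v)])
    }
    path_cache[[target]] <- paths
    paths
  }

  rows <- lapply(model$reactions$id, function(rid) {
    ci <- carbon_index(model, rid, cofactors)
    if (is.na(ci$x))
      return(data.frame(reaction_id = rid, indexable = FALSE,
                        n_c = NA_real_, x = NA_real_, entries = NA_character_))
    sto <- model$S[, rid]
    subs <- names(sto)[sto < 0]
    subs <- subs[!.is_cofactor(subs, cofactors)]
    tags <- character(0)
    n_seen <- 0
    for (s in subs) {
      paths <- routes_to(s)
      for (pp in paths) {
        n_seen <- n_seen + 1
        if (n_seen > max_routes) {
          warning("reaction ", rid, ": route enumeration capped at ",
                  max_routes, " routes; index computed on the truncated set")
          break
        }
        upstream <- pp[-length(pp)]           # strictly before the substrate
        n_conv <- length(intersect(upstream, conv))
        letter <- c("A", "B", "C", "D")[min(n_conv, 3) + 1]
        from_pyr <- !is.na(pyruvate) && pyruvate %in% pp
        tags <- c(tags, paste0(letter, if (from_pyr) "E" else ""))
      }
      if (n_seen > max_routes) break
    }
    if (length(tags) == 0)
      return(data.frame(reaction_id = rid, indexable = FALSE,
                        n_c = ci$n_c, x = ci$x, entries = NA_character_))
    entries <- sort(unique(paste0("C", format(ci$x, trim = TRUE), "J", tags)))
    data.frame(reaction_id = rid, indexable = TRUE, n_c = ci$n_c, x = ci$x,
               entries = paste(entries, collapse = "/"))
  })
  do.call(rbind, rows)
}

#' Write a CxJy index table as TSV
#'
#' @param index data.frame from [assign_cxjy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index_tsv <- function(index, path) {
  df <- index
  df$entries[!df$indexable] <- "unindexable"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build simultaneous on/off couplings from a group file
#'
#' One coupling per group; all member binaries are tied to a single group
#' indicator, with activation bounds taken from the model's original
#' reaction bounds (correct for reversible members with negative lower
#' bounds): all members off means all member fluxes zero, all on recovers the
#' original bounds.
#'
#' @param groups a [reaction_groups()] object.
#' @param model a [metabolic_model()].
#' @return Named list of couplings (`members`, `lower`, `upper`).
#' @export
build_on_off <- function(groups, model) {
  members <- group_members(groups)
  lapply(members, function(ids) {
    j <- match(ids, model$reactions$id)
    if (anyNA(j)) stop("group member not in model: ",
                       paste(ids[is.na(j)], collapse = ", "))
    list(members = ids, lower = model$reactions$lower[j],
         upper = model$reactions$upper[j])
  })
}

#' Build flux-scale couplings for index-equivalent group pairs
#'
#' Emits one coupling per within-group reaction pair whose CxJy entry sets
#' are equal as sets.  The coupled constraint keeps the two
#' uptake-normalised fluxes within `delta` of their common midpoint, which
#' for a pair is exactly the linear band
#' `|v1 - v2| <= delta * sqrt(2) * v_uptake`.
#'
#' @param groups a [reaction_groups()] object.
#' @param index data.frame from [assign_cxjy()].
#' @param delta flux-level constant (dimensionless, recommended 0.3).
#' @param model a [metabolic_model()].
#' @return data.frame with columns `r1`, `r2`, `delta` (zero rows when no
#'   pair qualifies).  Pairs with an unindexable member are skipped with a
#'   warning.
#' @export
build_scale <- function(groups, index, delta = 0.3, model = NULL) {
  stopifnot(delta > 0)
  entry_set <- function(rid) {
    row <- index[index$reaction_id == rid, , drop = FALSE]
    if (nrow(row) == 0 || !row$indexable) return(NULL)
    sort(strsplit(row$entries, "/", fixed = TRUE)[[1]])
  }
  out <- data.frame(r1 = character(0), r2 = character(0), delta = numeric(0))
  for (ids in group_members(groups)) {
    if (length(ids) < 2) next
    pairs <- utils::combn(sort(ids), 2)
    for (k in seq_len(ncol(pairs))) {
      e1 <- entry_set(pairs[1, k]); e2 <- entry_set(pairs[2, k])
      if (is.null(e1) || is.null(e2)) {
        warning("scale coupling skipped, unindexable member in pair (",
                pairs[1, k], ", ", pairs[2, k], ")")
        next
      }
      if (identical(e1, e2))
        out <- rbind(out, data.frame(r1 = pairs[1, k], r2 = pairs[2, k],
                                     delta = delta))
    }
  }
  out[!duplicated(out[, c("r1", "r2")]), , drop = FALSE]
}

#' Evaluate the flux-scale coupling left-hand side
#'
#' For a pair of uptake-normalised fluxes, the root-sum-square deviation from
#' their midpoint; the coupling requires this to be at most `delta`.
#'
#' @param v1n,v2n normalised fluxes (flux / carbon uptake rate).
#' @return numeric left-hand side.
#' @export
scale_coupling_lhs <- function(v1n, v2n) {
  m <- (v1n + v2n) / 2
  sqrt((v1n - m)^2 + (v2n - m)^2)
}

#' Bundle on/off and flux-scale couplings into a GR constraint set
#'
#' @param on_off list from [build_on_off()].
#' @param scale data.frame from [build_scale()].
#' @param scope optional reaction id set the constraints were restricted to.
#' @return A `gr_constraint_set` object.
#' @export
gr_constraint_set <- function(on_off = list(), scale = NULL, scope = NULL) {
  if (is.null(scale))
    scale <- data.frame(r1 = character(0), r2 = character(0), delta = numeric(0))
  structure(list(on_off = on_off, scale = scale, scope = scope),
            class = "gr_constraint_set")
}

#' @export
print.gr_constraint_set <- function(x, ...) {
  cat("gr_constraint_set:", length(x$on_off), "on/off group(s),",
      nrow(x$scale), "scale pair(s)\n")
  invisible(x)
}

#' Build the full GR constraint set for a model and group file
#'
#' Convenience wrapper: computes the CxJy index, then the on/off and
#' flux-scale couplings.  An optional `scope` restricts the groups to a
#' reaction neighbourhood (members outside the scope are removed, groups
#' reduced below two members are dropped), matching the practice of applying
#' GR constraints to the reactions around the biosynthesis of the target.
#'
#' @inheritParams assign_cxjy
#' @param groups a [reaction_groups()] object.
#' @param delta flux-scale constant.
#' @param scope optional character vector of reaction ids.
#' @return A [gr_constraint_set()].
#' @export
build_gr_constraints <- function(model, groups, carbon_source,
                                 cofactors = default_cofactors(),
                                 delta = 0.3, scope = NULL, pyruvate = NULL) {
  if (!is.null(scope)) {
    df <- as.data.frame(groups)
    df <- df[df$reaction_id %in% scope, , drop = FALSE]
    groups <- suppressWarnings(reaction_groups(df))
  }
  index <- assign_cxjy(model, carbon_source, cofactors, pyruvate = pyruvate)
  gr_constraint_set(on_off = build_on_off(groups, model),
                    scale = build_scale(groups, index, delta, model),
                    scope = scope)
}
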