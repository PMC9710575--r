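# Reaction-network representation: ordered species/reactions/parameters,
# exact-rational stoichiometric and kinetic matrices, and the exact network
# rank.

#' Build a reaction network from a raw SBML model
#'
#' Maps every SBML reaction to one reaction record with exact-rational
#' reactant and product stoichiometries. The parameter list is ordered the
#' way canonical naming requires: global parameters in document order, then
#' compartments, then lifted reaction-local parameters in reaction order.
#' Boundary (or constant) species keep their rows; their constancy is
#' enforced at ODE assembly, not here.
#'
#' @param model a `raw_sbml` model that passed [check_supported()], with
#'   function definitions inlined and local parameters lifted.
#' @return an object of class `reaction_network`.
#' @export
build_network <- function(model) {
  sp_ids <- model_species_ids(model)
  sp_index <- stats::setNames(seq_along(sp_ids), sp_ids)

  species <- lapply(model$species, function(s) {
    list(
      id = s$id,
      compartment = s$compartment,
      boundary = isTRUE(s$boundary_condition) || isTRUE(s$constant),
      has_assignment_rule = s$id %in% names(model$assignment_rules),
      has_rate_rule = s$id %in% names(model$rate_rules),
      substance_units_is_amount = isTRUE(s$substance_units_is_amount)
    )
  })

  stoich_map <- function(refs, rid) {
    idx <- integer(0)
    coef <- list()
    for (sr in refs) {
      i <- sp_index[[sr$species]]
      if (is.null(i) || is.na(i)) stop("reaction '", rid, "' references unknown species '", sr$species, "'")
      q <- literal_to_rational(sr$stoich_lex)
      pos <- match(i, idx)
      if (is.na(pos)) {
        idx <- c(idx, i)
        coef[[length(coef) + 1L]] <- q
      } else {
        coef[[pos]] <- rq_add(coef[[pos]], q)
      }
    }
    list(index = idx, coef = coef)
  }

  reactions <- lapply(model$reactions, function(rx) {
    for (m in rx$modifiers) {
      if (!(m %in% sp_ids)) stop("reaction '", rx$id, "' references unknown modifier '", m, "'")
    }
    list(
      id = rx$id,
      reactant_stoich = stoich_map(rx$reactants, rx$id),
      product_stoich = stoich_map(rx$products, rx$id),
      modifiers = rx$modifiers,
      reversible = isTRUE(rx$reversible),
      kinetic_law = rx$kinetic_law
    )
  })

  globals <- Filter(function(p) identical(p$origin, "global"), model$parameters)
  lifted <- Filter(function(p) !identical(p$origin, "global"), model$parameters)
  rx_order <- vapply(model$reactions, `[[`, character(1), "id")
  if (length(lifted)) {
    lifted <- lifted[order(match(vapply(lifted, `[[`, character(1), "origin"), rx_order))]
  }
  pval <- function(lex, default = NULL) {
    if (is.na(lex)) return(default)
    literal_to_rational(lex)
  }
  parameters <- c(
    lapply(globals, function(p) list(id = p$id, value = pval(p$value_lex), origin = "global")),
    lapply(model$compartments, function(cmp) {
      list(
        id = cmp$id,
        value = pval(if (is.na(cmp$size_lex)) "1" else cmp$size_lex, rq_one()),
        origin = "compartment"
      )
    }),
    lapply(lifted, function(p) list(id = p$id, value = pval(p$value_lex), origin = p$origin))
  )

  structure(
    list(species = species, reactions = reactions, parameters = parameters),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(
    "reaction network: %d species, %d reactions, %d parameters\n",
    length(x$species), length(x$reactions), length(x$parameters)
  ))
  invisible(x)
}

#' Exact stoichiometric matrix of a reaction network
#'
#' `S[i, j]` is the net stoichiometric change (product coefficient minus
#' reactant coefficient) of species `i` in reaction `j`, as an exact
#' rational. Row order is species document order; column order is reaction
#' order; boundary species keep their rows.
#'
#' @param net a `reaction_network`.
#' @return an n-by-r list-matrix of exact rationals; use
#'   [rational_matrix_to_character()] or [rational_matrix_to_numeric()] to
#'   inspect it.
#' @export
stoichiometric_matrix <- function(net) {
  n <- length(net$species)
  r <- length(net$reactions)
  S <- rmat_new(n, r)
  for (j in seq_len(r)) {
    rx <- net$reactions[[j]]
    rs <- rx$reactant_stoich
    for (k in seq_along(rs$index)) {
      i <- rs$index[k]
      S[[i, j]] <- rq_sub(S[[i, j]], rs$coef[[k]])
    }
    ps <- rx$product_stoich
    for (k in seq_along(ps$index)) {
      i <- ps$index[k]
      S[[i, j]] <- rq_add(S[[i, j]], ps$coef[[k]])
    }
  }
  S
}

#' Exact kinetic (reactant-order) matrix of a reaction network
#'
#' `K[i, j]` is the reactant-side stoichiometric coefficient of species `i`
#' in reaction `j` (0 if absent) -- the kinetic-order matrix of chemical
#' reaction network theory. An empty reactant side (an inflow reaction)
#' yields a zero column.
#'
#' @inheritParams stoichiometric_matrix
#' @return an n-by-r list-matrix of exact rationals.
#' @export
kinetic_matrix <- function(net) {
  n <- length(net$species)
  r <- length(net$reactions)
  K <- rmat_new(n, r)
  for (j in seq_len(r)) {
    rs <- net$reactions[[j]]$reactant_stoich
    for (k in seq_along(rs$index)) {
      K[[rs$index[k], j]] <- rs$coef[[k]]
    }
  }
  K
}

#' Exact rank of a stoichiometric matrix
#'
#' Computed over the rationals by fraction-free (Bareiss-style) elimination,
#' so no rounding can change the answer.
#'
#' @param S an exact rational list-matrix, as from [stoichiometric_matrix()].
#' @return the rank as a nonnegative integer.
#' @export
network_rank <- function(S) {
  rmat_rank(S)
}

#' Convert an exact rational matrix to a character matrix
#'
#' @param M a list-matrix of exact rationals.
#' @return a character matrix of `"p/q"` strings.
#' @export
rational_matrix_to_character <- function(M) rmat_to_char(M)

#' Convert an exact rational matrix to a numeric (double) matrix
#'
#' Only for inspection and numeric cross-checks; the conversion rounds.
#'
#' @param M a list-matrix of exact rationals.
#' @return a numeric matrix.
#' @export
rational_matrix_to_numeric <- function(M) rmat_to_num(M)

# indices of dynamic species: neither boundary/constant nor defined by an
# assignment rule (rate-rule species are dynamic but not reaction-driven;
# they are excluded from conservation analysis as their dynamics are
# arbitrary expressions, not stoichiometric flows)
dynamic_species_indices <- function(net, include_rate_rule = FALSE) {
  keep <- vapply(net$species, function(s) {
    !s$boundary && !s$has_assignment_rule && (include_rate_rule || !s$has_rate_rule)
  }, logical(1))
  which(keep)
}
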