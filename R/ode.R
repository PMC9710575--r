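# ODE assembly: canonical renaming (x1..xn / k1..km), explicit first-order
# ODEs for species concentrations, exact value resolution, and formal
# constraints from species assignment rules.

#' Build the canonical name map of a reaction network
#'
#' Species are named `x1, ..., xn` in document order; parameters are named
#' `k1, ..., km` with global parameters first (document order), then
#' compartments, then lifted reaction-local parameters in reaction order.
#' The map is a bijection in both directions.
#'
#' @param net a `reaction_network` from [build_network()].
#' @return an object of class `name_map` with fields `species`,
#'   `parameters` (named character vectors, SBML id -> mathematical name)
#'   and `inv` (the inverse map).
#' @export
build_name_map <- function(net) {
  sp_ids <- vapply(net$species, `[[`, character(1), "id")
  par_ids <- vapply(net$parameters, `[[`, character(1), "id")
  species <- stats::setNames(paste0("x", seq_along(sp_ids)), sp_ids)
  parameters <- stats::setNames(paste0("k", seq_along(par_ids)), par_ids)
  all_map <- c(species, parameters)
  structure(
    list(
      species = species,
      parameters = parameters,
      all = all_map,
      inv = stats::setNames(names(all_map), unname(all_map))
    ),
    class = "name_map"
  )
}

#' @export
print.name_map <- function(x, ...) {
  cat("name map:\n")
  for (i in seq_along(x$species)) {
    cat(sprintf("  %s <-> %s\n", unname(x$species[i]), names(x$species)[i]))
  }
  for (i in seq_along(x$parameters)) {
    cat(sprintf("  %s <-> %s\n", unname(x$parameters[i]), names(x$parameters)[i]))
  }
  invisible(x)
}

# species assignment rules as a substitution environment over SBML ids,
# iterated to closure with cycle detection
species_assignment_env <- function(model) {
  sp_ids <- model_species_ids(model)
  asg <- model$assignment_rules[intersect(names(model$assignment_rules), sp_ids)]
  if (!length(asg)) return(list())
  env <- asg
  for (rep in seq_len(length(asg) + 1L)) {
    env2 <- lapply(env, function(e) ex_subst(e, env))
    if (identical(env2, env)) break
    env <- env2
  }
  for (id in names(env)) {
    if (ex_uses_any(env[[id]], names(env))) {
      stop("cyclic assignment-rule dependencies involving species '", id, "'")
    }
  }
  env
}

#' Assemble the explicit first-order ODE system of a model
#'
#' For each non-boundary species without a rule, the right-hand side is the
#' stoichiometry-weighted sum of the reaction rates, rewritten in canonical
#' `x`/`k` names and divided by the (constant, rational) size of the
#' species' compartment, so the equations govern concentrations. Boundary
#' and constant species get a zero right-hand side; species with rate rules
#' get the rule expression (possibly time-dependent, making the system
#' non-autonomous); species defined by assignment rules get no ODE -- they
#' are substituted into the kinetic laws and survive as formal constraints.
#'
#' @param net a `reaction_network`.
#' @param model the originating `raw_sbml` model (for rules).
#' @param nm the `name_map` from [build_name_map()].
#' @param divide_by_compartment divide reaction terms by the compartment
#'   size (the amount-rate to concentration-rate conversion). Default TRUE.
#' @return an object of class `ode_system`.
#' @export
assemble_odes <- function(net, model, nm, divide_by_compartment = TRUE) {
  sp_ids <- vapply(net$species, `[[`, character(1), "id")
  asg_env <- species_assignment_env(model)

  comp_size <- list()
  for (p in net$parameters) {
    if (identical(p$origin, "compartment")) comp_size[[p$id]] <- p$value
  }

  S <- stoichiometric_matrix(net)
  prep <- function(e) ex_rename(ex_subst(e, asg_env), nm$all)

  laws <- lapply(net$reactions, function(rx) prep(rx$kinetic_law))

  equations <- list()
  for (i in seq_along(net$species)) {
    sp <- net$species[[i]]
    xi <- unname(nm$species[[sp$id]])
    if (sp$has_assignment_rule) next
    if (sp$has_rate_rule) {
      equations[[xi]] <- prep(model$rate_rules[[sp$id]])
      next
    }
    if (sp$boundary) {
      equations[[xi]] <- ex_num(rq_zero())
      next
    }
    size <- rq_one()
    if (divide_by_compartment && !sp$substance_units_is_amount && !is.na(sp$compartment) &&
      !is.null(comp_size[[sp$compartment]])) {
      size <- comp_size[[sp$compartment]]
    }
    terms <- list()
    for (j in seq_along(net$reactions)) {
      cij <- S[[i, j]]
      if (rq_is_zero(cij)) next
      coeff <- rq_div(cij, size)
      v <- laws[[j]]
      term <- if (rq_is_one(coeff)) {
        v
      } else if (rq_eq(coeff, rq_int(-1))) {
        e_neg(v)
      } else {
        e_mul(ex_num(coeff), v)
      }
      terms[[length(terms) + 1L]] <- term
    }
    equations[[xi]] <- e_sum(terms)
  }

  uses_time <- any(vapply(equations, function(e) ex_free(e)$time, logical(1)))

  structure(
    list(
      variables = unname(nm$species),
      equations = equations,
      kinetic_laws = laws,
      name_map = nm,
      autonomous = !uses_time
    ),
    class = "ode_system"
  )
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf(
    "ODE system: %d variables, %d equations (%s)\n",
    length(x$variables), length(x$equations),
    if (x$autonomous) "autonomous" else "non-autonomous"
  ))
  for (v in names(x$equations)) {
    cat(sprintf("  d%s/dt = %s\n", v, ex_render(x$equations[[v]], "plain")))
  }
  invisible(x)
}

#' Resolve exact parameter values and species initial values
#'
#' SBML precedence is honoured: an initial assignment wins over an
#' assignment rule, which wins over the declared attribute value; initial
#' amounts are divided by the compartment size to give concentrations
#' (unless the species is amount-based). Evaluation follows dependency
#' order, all in exact rational arithmetic.
#'
#' @param model a supported `raw_sbml` model (functions inlined, locals
#'   lifted).
#' @param nm the `name_map`.
#' @return `list(parameter_values = <named list of rq by k-name>,
#'   initial_values = <named list of rq by x-name; NULL when unspecified>)`.
#' @export
resolve_values <- function(model, nm) {
  consts <- model_constant_report(model)
  getval <- function(id) {
    st <- consts[[id]]
    if (inherits(st, "const_eval") && !st$irrational) st$value else NULL
  }

  parameter_values <- list()
  for (id in names(nm$parameters)) {
    v <- getval(id)
    if (!is.null(v)) parameter_values[[unname(nm$parameters[[id]])]] <- v
  }

  comp_size <- list()
  for (cmp in model$compartments) {
    v <- getval(cmp$id)
    comp_size[[cmp$id]] <- if (is.null(v)) rq_one() else v
  }

  initial_values <- list()
  for (s in model$species) {
    xi <- unname(nm$species[[s$id]])
    v <- getval(s$id)
    if (is.null(v)) next
    from_amount <- is.null(model$initial_assignments[[s$id]]) &&
      is.na(s$initial_concentration_lex) && !is.na(s$initial_amount_lex)
    if (from_amount && !s$substance_units_is_amount) {
      size <- comp_size[[s$compartment]]
      if (!is.null(size) && !rq_is_zero(size)) v <- rq_div(v, size)
    }
    initial_values[[xi]] <- v
  }

  list(parameter_values = parameter_values, initial_values = initial_values)
}

#' Formal constraints from species assignment rules
#'
#' Each SBML species assignment rule becomes one formal constraint
#' `xi = g(x, k, t)` with `g` rewritten in canonical names and exact
#' rational constants.
#'
#' @param model a supported `raw_sbml` model.
#' @param nm the `name_map`.
#' @return a list of constraints, each
#'   `list(kind = "species-assignment", lhs, rhs, origin)` with `lhs`/`rhs`
#'   expression trees.
#' @export
species_assignment_constraints <- function(model, nm) {
  sp_ids <- model_species_ids(model)
  targets <- intersect(names(model$assignment_rules), sp_ids)
  lapply(targets, function(id) {
    list(
      kind = "species-assignment",
      lhs = ex_sym(unname(nm$species[[id]])),
      rhs = ex_rename(model$assignment_rules[[id]], nm$all),
      origin = id
    )
  })
}
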