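# SBML ingest: parse Level 2/3 documents into a raw model, gate unsupported
# features, inline function definitions and lift reaction-local parameters.
#
# Only the features needed for exact symbolic conversion are read; lexical
# numeric strings are preserved verbatim so the exact-arithmetic layer can
# convert decimal text instead of binary doubles.

#' Parse an SBML document into a raw model
#'
#' Reads an SBML Level 2 or Level 3 document (file path or XML text) into a
#' raw model: species, reactions, global/local parameters, compartments,
#' rules, initial assignments and function definitions, with all numeric
#' attribute values kept as their original lexical strings and MathML
#' kinetic laws converted to expression trees.
#'
#' @param input path to an SBML file, or a character scalar holding the XML.
#' @return an object of class `raw_sbml`.
#' @export
parse_sbml <- function(input) {
  doc <- tryCatch(
    xml2::read_xml(input),
    error = function(e) stop("XML parse error: ", conditionMessage(e), call. = FALSE)
  )
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("not an SBML document (root element <", root, ">)")
  level <- suppressWarnings(as.integer(xml2::xml_attr(doc, "level")))
  version <- suppressWarnings(as.integer(xml2::xml_attr(doc, "version")))
  if (is.na(level)) stop("not an SBML document: missing level attribute")
  if (level == 1) stop("SBML Level 1 is not supported")
  if (!(level %in% c(2L, 3L))) stop("unsupported SBML level: ", level)
  xml2::xml_ns_strip(doc)

  mnode <- xml2::xml_find_first(doc, "./model")
  if (inherits(mnode, "xml_missing")) stop("not an SBML document: missing <model>")

  attr_or_na <- function(node, name) xml2::xml_attr(node, name)
  attr_flag <- function(node, name, default) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else identical(v, "true")
  }

  math_issues <- character(0)
  read_math <- function(node) {
    m <- xml2::xml_find_first(node, "./math")
    if (inherits(m, "xml_missing")) return(NULL)
    e <- mathml_to_ex(m)
    uh <- ex_unknown_heads(e)
    if (length(uh)) math_issues <<- c(math_issues, uh)
    e
  }

  order_counter <- 0L
  next_order <- function() {
    order_counter <<- order_counter + 1L
    order_counter
  }

  compartments <- lapply(xml2::xml_find_all(mnode, "./listOfCompartments/compartment"), function(nd) {
    list(
      id = attr_or_na(nd, "id"),
      size_lex = {
        v <- attr_or_na(nd, "size")
        if (is.na(v)) v <- attr_or_na(nd, "volume")
        v
      },
      constant = attr_flag(nd, "constant", TRUE),
      doc_order = next_order()
    )
  })

  species <- lapply(xml2::xml_find_all(mnode, "./listOfSpecies/species"), function(nd) {
    amt <- attr_or_na(nd, "initialAmount")
    conc <- attr_or_na(nd, "initialConcentration")
    if (!is.na(amt) && !is.na(conc)) stop("species ", attr_or_na(nd, "id"), ": both initialAmount and initialConcentration set")
    list(
      id = attr_or_na(nd, "id"),
      compartment = attr_or_na(nd, "compartment"),
      boundary_condition = attr_flag(nd, "boundaryCondition", FALSE),
      constant = attr_flag(nd, "constant", FALSE),
      initial_amount_lex = amt,
      initial_concentration_lex = conc,
      substance_units_is_amount = attr_flag(nd, "hasOnlySubstanceUnits", FALSE),
      doc_order = next_order()
    )
  })

  parameters <- lapply(xml2::xml_find_all(mnode, "./listOfParameters/parameter"), function(nd) {
    list(
      id = attr_or_na(nd, "id"),
      value_lex = attr_or_na(nd, "value"),
      constant = attr_flag(nd, "constant", TRUE),
      origin = "global",
      doc_order = next_order()
    )
  })

  function_definitions <- list()
  for (nd in xml2::xml_find_all(mnode, "./listOfFunctionDefinitions/functionDefinition")) {
    id <- attr_or_na(nd, "id")
    lam <- xml2::xml_find_first(nd, "./math/lambda")
    if (inherits(lam, "xml_missing")) stop("function definition ", id, ": missing <lambda>")
    kids <- xml2::xml_children(lam)
    bvars <- character(0)
    body <- NULL
    for (k in kids) {
      if (xml2::xml_name(k) == "bvar") {
        bvars <- c(bvars, trimws(xml2::xml_text(k)))
      } else {
        body <- mathml_to_ex(k)
      }
    }
    if (is.null(body)) stop("function definition ", id, ": missing body")
    uh <- ex_unknown_heads(body)
    if (length(uh)) math_issues <- c(math_issues, uh)
    function_definitions[[id]] <- list(args = bvars, body = body)
  }

  assignment_rules <- list()
  rate_rules <- list()
  n_algebraic <- 0L
  for (nd in xml2::xml_find_all(mnode, "./listOfRules/*")) {
    nm <- xml2::xml_name(nd)
    if (nm == "algebraicRule") {
      n_algebraic <- n_algebraic + 1L
      next
    }
    target <- attr_or_na(nd, "variable")
    expr <- read_math(nd)
    if (nm == "assignmentRule") assignment_rules[[target]] <- expr
    if (nm == "rateRule") rate_rules[[target]] <- expr
  }

  initial_assignments <- list()
  for (nd in xml2::xml_find_all(mnode, "./listOfInitialAssignments/initialAssignment")) {
    initial_assignments[[attr_or_na(nd, "symbol")]] <- read_math(nd)
  }

  read_spec_refs <- function(rnode, path) {
    lapply(xml2::xml_find_all(rnode, path), function(sr) {
      sm <- xml2::xml_find_first(sr, "./stoichiometryMath")
      list(
        species = attr_or_na(sr, "species"),
        stoich_lex = {
          v <- attr_or_na(sr, "stoichiometry")
          if (is.na(v)) "1" else v
        },
        stoichiometry_math = !inherits(sm, "xml_missing")
      )
    })
  }

  reactions <- lapply(xml2::xml_find_all(mnode, "./listOfReactions/reaction"), function(nd) {
    klaw <- xml2::xml_find_first(nd, "./kineticLaw")
    law_expr <- NULL
    locals <- list()
    if (!inherits(klaw, "xml_missing")) {
      law_expr <- read_math(klaw)
      locs <- c(
        xml2::xml_find_all(klaw, "./listOfParameters/parameter"),
        xml2::xml_find_all(klaw, "./listOfLocalParameters/localParameter")
      )
      locals <- lapply(locs, function(p) {
        list(
          id = attr_or_na(p, "id"),
          value_lex = attr_or_na(p, "value"),
          constant = TRUE,
          origin = "local"
        )
      })
    }
    list(
      id = attr_or_na(nd, "id"),
      reactants = read_spec_refs(nd, "./listOfReactants/speciesReference"),
      products = read_spec_refs(nd, "./listOfProducts/speciesReference"),
      modifiers = vapply(
        xml2::xml_find_all(nd, "./listOfModifiers/modifierSpeciesReference"),
        function(x) attr_or_na(x, "species"), character(1)
      ),
      reversible = attr_flag(nd, "reversible", TRUE),
      kinetic_law = law_expr,
      local_parameters = locals,
      doc_order = next_order()
    )
  })

  ids <- c(
    vapply(species, `[[`, character(1), "id"),
    vapply(parameters, `[[`, character(1), "id"),
    vapply(compartments, `[[`, character(1), "id")
  )
  if (anyDuplicated(ids)) {
    stop("duplicate entity ids in document: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  model <- structure(
    list(
      level = level,
      version = version,
      model_id = attr_or_na(mnode, "id"),
      compartments = compartments,
      species = species,
      parameters = parameters,
      reactions = reactions,
      function_definitions = function_definitions,
      assignment_rules = assignment_rules,
      rate_rules = rate_rules,
      n_algebraic_rules = n_algebraic,
      initial_assignments = initial_assignments,
      events_present = length(xml2::xml_find_all(mnode, "./listOfEvents/event")) > 0,
      constraints_present = length(xml2::xml_find_all(mnode, "./listOfConstraints/constraint")) > 0,
      math_issues = unique(math_issues)
    ),
    class = "raw_sbml"
  )

  # every rule / initial-assignment target must name an entity
  known <- c(ids, names(function_definitions))
  for (tgt in unique(c(names(assignment_rules), names(rate_rules), names(initial_assignments)))) {
    if (!(tgt %in% known)) stop("rule or initial assignment targets unknown id: ", tgt)
  }
  model
}

#' @export
print.raw_sbml <- function(x, ...) {
  cat(sprintf(
    "SBML L%dV%d raw model: %d species, %d reactions, %d parameters, %d compartments\n",
    x$level, x$version, length(x$species), length(x$reactions),
    length(x$parameters), length(x$compartments)
  ))
  invisible(x)
}

model_species_ids <- function(model) vapply(model$species, `[[`, character(1), "id")
model_parameter_ids <- function(model) vapply(model$parameters, `[[`, character(1), "id")
model_compartment_ids <- function(model) vapply(model$compartments, `[[`, character(1), "id")

# attempt exact evaluation of all constant entities (parameters, compartment
# sizes, species initials, dependency-ordered); used by the support check
model_constant_report <- function(model) {
  sp_ids <- model_species_ids(model)
  par_ids <- model_parameter_ids(model)
  comp_ids <- model_compartment_ids(model)

  defs <- model$function_definitions
  safe_inline <- function(e) {
    tryCatch(inline_function_definitions(e, defs), error = function(err) err)
  }

  # candidate constant definition per entity id
  exprs <- list()
  for (p in model$parameters) {
    id <- p$id
    e <- model$initial_assignments[[id]]
    if (is.null(e)) e <- model$assignment_rules[[id]]
    if (is.null(e) && !is.na(p$value_lex)) {
      e <- tryCatch(ex_num(literal_to_rational(p$value_lex), lex = p$value_lex), error = function(err) err)
    }
    exprs[[id]] <- e
  }
  for (cmp in model$compartments) {
    id <- cmp$id
    e <- model$initial_assignments[[id]]
    if (is.null(e)) e <- model$assignment_rules[[id]]
    if (is.null(e)) {
      lex <- if (is.na(cmp$size_lex)) "1" else cmp$size_lex
      e <- tryCatch(ex_num(literal_to_rational(lex), lex = lex), error = function(err) err)
    }
    exprs[[id]] <- e
  }
  for (s in model$species) {
    id <- s$id
    e <- model$initial_assignments[[id]]
    if (is.null(e)) {
      lex <- if (!is.na(s$initial_concentration_lex)) s$initial_concentration_lex else s$initial_amount_lex
      if (!is.na(lex)) {
        e <- tryCatch(ex_num(literal_to_rational(lex), lex = lex), error = function(err) err)
      }
    }
    exprs[[id]] <- e
  }

  status <- list() # id -> const_eval | "nonconstant" | "invalid" | "cycle" | NULL
  visiting <- character(0)
  resolve <- function(id) {
    if (!is.null(status[[id]])) return(status[[id]])
    e <- exprs[[id]]
    if (is.null(e)) {
      status[[id]] <<- "unset"
      return("unset")
    }
    if (inherits(e, "error") || inherits(e, "condition")) {
      status[[id]] <<- "invalid"
      return("invalid")
    }
    if (id %in% visiting) {
      status[[id]] <<- "cycle"
      return("cycle")
    }
    visiting <<- c(visiting, id)
    on.exit(visiting <<- setdiff(visiting, id), add = TRUE)
    e <- safe_inline(e)
    if (inherits(e, "error")) {
      status[[id]] <<- "invalid"
      return("invalid")
    }
    fr <- ex_free(e)
    if (fr$time) {
      status[[id]] <<- "nonconstant"
      return("nonconstant")
    }
    env <- list()
    for (dep in fr$syms) {
      if (!(dep %in% c(par_ids, comp_ids, sp_ids))) {
        status[[id]] <<- "invalid"
        return("invalid")
      }
      ds <- resolve(dep)
      if (identical(ds, "cycle")) {
        status[[id]] <<- "cycle"
        return("cycle")
      }
      if (is.character(ds)) {
        status[[id]] <<- "nonconstant"
        return("nonconstant")
      }
      if (ds$irrational) {
        status[[id]] <<- ds
        return(ds)
      }
      env[[dep]] <- ds$value
    }
    # a species feeding the expression makes it constant only at t=0; that is
    # fine for initial assignments, which is the only context species reach
    res <- tryCatch(eval_constant(e, env), error = function(err) "invalid")
    status[[id]] <<- res
    res
  }
  for (id in names(exprs)) resolve(id)
  status
}

#' Check a raw model against the supported SBML feature set
#'
#' The converter covers species with boundary conditions, local parameters,
#' parameter and species assignment rules, parameter and species initial
#' assignments, species rate rules and function definitions. Documents using
#' events, parameter rate rules, algebraic rules, constraint elements,
#' non-constant compartments, unsupported math constructs, or constants that
#' are provably irrational (for example a parameter set to `exp(1)`) are
#' reported as unsupported, with one violation per occurrence.
#'
#' @param model a `raw_sbml` model from [parse_sbml()].
#' @return an object of class `support_report`: `list(supported = <flag>,
#'   violations = <data.frame feature/id/message>)`.
#' @export
check_supported <- function(model) {
  v <- list()
  add <- function(feature, id, message) {
    v[[length(v) + 1L]] <<- data.frame(
      feature = feature, id = id, message = message, stringsAsFactors = FALSE
    )
  }

  if (model$events_present) {
    add("events", "", "model contains SBML events")
  }
  if (model$constraints_present) {
    add("constraint element", "", "model contains SBML constraint elements")
  }
  if (model$n_algebraic_rules > 0) {
    add("algebraic rule", "", sprintf("model contains %d algebraic rule(s)", model$n_algebraic_rules))
  }
  par_ids <- model_parameter_ids(model)
  comp_ids <- model_compartment_ids(model)
  sp_ids <- model_species_ids(model)
  for (tgt in names(model$rate_rules)) {
    if (tgt %in% par_ids) {
      add("parameter rate rule", tgt, sprintf("rate rule targets parameter '%s'", tgt))
    }
    if (tgt %in% comp_ids) {
      add("non-constant compartment", tgt, sprintf("rate rule targets compartment '%s'", tgt))
    }
  }
  for (cmp in model$compartments) {
    if (!cmp$constant || !is.null(model$assignment_rules[[cmp$id]])) {
      add("non-constant compartment", cmp$id, sprintf("compartment '%s' is not constant", cmp$id))
    }
  }
  for (rx in model$reactions) {
    if (is.null(rx$kinetic_law)) {
      add("missing kinetic law", rx$id, sprintf("reaction '%s' has no kinetic law", rx$id))
    }
    for (sr in c(rx$reactants, rx$products)) {
      if (isTRUE(sr$stoichiometry_math)) {
        add("stoichiometry math", rx$id, sprintf("reaction '%s' uses stoichiometryMath", rx$id))
      } else {
        ok <- tryCatch(
          rq_sign(literal_to_rational(sr$stoich_lex)) > 0,
          error = function(e) FALSE
        )
        if (!ok) {
          add("invalid stoichiometry", rx$id, sprintf(
            "reaction '%s': stoichiometry '%s' is not a positive rational", rx$id, sr$stoich_lex
          ))
        }
      }
    }
  }
  for (head in model$math_issues) {
    add("unsupported math", "", sprintf("unsupported MathML construct <%s>", head))
  }
  # recursive function definitions
  defs <- model$function_definitions
  if (length(defs)) {
    err <- tryCatch(
      {
        inline_function_definitions(ex_num(0), defs) # runs the cycle check
        NULL
      },
      error = function(e) conditionMessage(e)
    )
    if (!is.null(err)) add("recursive function definitions", "", err)
  }
  # exact evaluation of constants: irrational / invalid / cyclic
  consts <- tryCatch(model_constant_report(model), error = function(e) NULL)
  if (is.null(consts)) {
    add("constant evaluation", "", "constant entities could not be evaluated")
  } else {
    for (id in names(consts)) {
      st <- consts[[id]]
      if (identical(st, "invalid")) {
        add("invalid numeric literal", id, sprintf("value of '%s' is not a finite numeral", id))
      } else if (identical(st, "cycle")) {
        add("cyclic assignment", id, sprintf("assignments defining '%s' are cyclic", id))
      } else if (inherits(st, "const_eval") && st$irrational) {
        kind <- if (id %in% sp_ids) "irrational initial value" else "irrational parameter value"
        add(kind, id, sprintf("value of '%s' is irrational (%s)", id, st$reason))
      }
    }
  }

  violations <- if (length(v)) do.call(rbind, v) else {
    data.frame(feature = character(0), id = character(0), message = character(0), stringsAsFactors = FALSE)
  }
  structure(
    list(supported = nrow(violations) == 0, violations = violations),
    class = "support_report"
  )
}

#' @export
print.support_report <- function(x, ...) {
  if (x$supported) {
    cat("supported: all features recognized\n")
  } else {
    cat("unsupported:", nrow(x$violations), "violation(s)\n")
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  - [%s] %s\n", x$violations$feature[i], x$violations$message[i]))
    }
  }
  invisible(x)
}

#' Lift reaction-local parameters to fresh global parameters
#'
#' Every reaction-local parameter becomes a global parameter with a fresh
#' unique id (the originating reaction is recorded as its origin), and the
#' reaction's kinetic law is rewritten to reference the lifted id. SBML
#' scoping is respected: a local parameter shadows a global of the same name
#' inside its own kinetic law only. Applying the operation twice equals
#' applying it once.
#'
#' @param model a `raw_sbml` model.
#' @return the model with no reaction-local parameters remaining.
#' @export
lift_local_parameters <- function(model) {
  taken <- c(
    model_species_ids(model), model_parameter_ids(model), model_compartment_ids(model)
  )
  for (i in seq_along(model$reactions)) {
    rx <- model$reactions[[i]]
    if (!length(rx$local_parameters)) next
    ren <- character(0)
    for (lp in rx$local_parameters) {
      fresh <- paste(rx$id, lp$id, sep = "_")
      while (fresh %in% taken) fresh <- paste0(fresh, "_l")
      taken <- c(taken, fresh)
      ren[[lp$id]] <- fresh
      model$parameters[[length(model$parameters) + 1L]] <- list(
        id = fresh,
        value_lex = lp$value_lex,
        constant = TRUE,
        origin = rx$id,
        doc_order = NA_integer_
      )
    }
    if (!is.null(rx$kinetic_law)) {
      rx$kinetic_law <- ex_rename(rx$kinetic_law, ren)
    }
    rx$local_parameters <- list()
    model$reactions[[i]] <- rx
  }
  model
}

# inline function definitions into every expression of the model
inline_model_functions <- function(model) {
  defs <- model$function_definitions
  if (!length(defs)) return(model)
  f <- function(e) if (is.null(e)) NULL else inline_function_definitions(e, defs)
  for (i in seq_along(model$reactions)) {
    model$reactions[[i]]$kinetic_law <- f(model$reactions[[i]]$kinetic_law)
  }
  model$assignment_rules <- lapply(model$assignment_rules, f)
  model$rate_rules <- lapply(model$rate_rules, f)
  model$initial_assignments <- lapply(model$initial_assignments, f)
  model$function_definitions <- list()
  model
}

# Parameters defined by assignment rules that reference species or time are
# derived quantities, not constants: substitute their definitions everywhere
# (dependency-ordered) and drop them from the parameter list.
substitute_nonconstant_parameter_rules <- function(model) {
  par_ids <- model_parameter_ids(model)
  sp_ids <- model_species_ids(model)
  rule_pars <- intersect(names(model$assignment_rules), par_ids)
  if (!length(rule_pars)) return(model)

  nonconst <- function(id, seen = character(0)) {
    e <- model$assignment_rules[[id]]
    fr <- ex_free(e)
    if (fr$time || any(fr$syms %in% sp_ids)) return(TRUE)
    deps <- intersect(fr$syms, rule_pars)
    deps <- setdiff(deps, seen)
    any(vapply(deps, function(d) nonconst(d, c(seen, id)), logical(1)))
  }
  subst_ids <- rule_pars[vapply(rule_pars, nonconst, logical(1))]
  if (!length(subst_ids)) return(model)

  # dependency-closed simultaneous substitution, iterated to a fixed point
  env <- model$assignment_rules[subst_ids]
  for (rep in seq_len(length(subst_ids) + 1L)) {
    env2 <- lapply(env, function(e) ex_subst(e, env))
    if (identical(env2, env)) break
    env <- env2
  }
  for (id in subst_ids) {
    if (ex_uses_any(env[[id]], subst_ids)) {
      stop("cyclic assignment-rule dependencies involving parameter '", id, "'")
    }
  }
  f <- function(e) if (is.null(e)) NULL else ex_subst(e, env)
  for (i in seq_along(model$reactions)) {
    model$reactions[[i]]$kinetic_law <- f(model$reactions[[i]]$kinetic_law)
  }
  keep <- setdiff(names(model$assignment_rules), subst_ids)
  model$assignment_rules <- lapply(model$assignment_rules[keep], f)
  model$rate_rules <- lapply(model$rate_rules, f)
  model$initial_assignments <- lapply(model$initial_assignments, f)
  model$parameters <- Filter(function(p) !(p$id %in% subst_ids), model$parameters)
  model
}
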