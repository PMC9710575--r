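# Top-level driver: one call from an SBML document to the complete symbolic
# dataset (ODEs, matrices, conservation laws, deficiency, classification,
# name map, exact values).

#' Convert an SBML model to an exact symbolic ODE dataset
#'
#' Runs the full pipeline: parse, feature gating, function-definition
#' inlining, local-parameter lifting, canonical renaming, exact value
#' resolution, ODE assembly, stoichiometric/kinetic matrices, linear
#' conservation laws, deficiency and kinetics classification. All numbers
#' in the result are exact rationals.
#'
#' @param input path to an SBML Level 2/3 file, or the XML text itself.
#' @param divide_by_compartment divide reaction rates by the compartment
#'   size so the ODEs govern concentrations (default TRUE; size-1
#'   compartments make this a no-op).
#' @param source_name label recorded in the dataset provenance; defaults to
#'   the file name (or `"<inline>"` for XML text input).
#' @return an object of class `ode_dataset`.
#' @examples
#' toy <- named_toys()[["iso"]]
#' ds <- sbml_to_ode(toy$sbml)
#' ds$deficiency$deficiency
#' @export
sbml_to_ode <- function(input, divide_by_compartment = TRUE, source_name = NULL) {
  if (is.null(source_name)) {
    source_name <- if (is.character(input) && !grepl("<", input, fixed = TRUE)) {
      basename(input)
    } else {
      "<inline>"
    }
  }
  model <- parse_sbml(input)
  support <- check_supported(model)
  if (!support$supported) {
    cond <- structure(
      class = c("sbml_unsupported", "error", "condition"),
      list(
        message = paste0(
          "model uses unsupported features: ",
          paste(unique(support$violations$feature), collapse = ", ")
        ),
        call = sys.call(),
        report = support
      )
    )
    stop(cond)
  }
  model <- inline_model_functions(model)
  model <- lift_local_parameters(model)
  model <- substitute_nonconstant_parameter_rules(model)

  net <- build_network(model)
  nm <- build_name_map(net)
  S <- stoichiometric_matrix(net)
  K <- kinetic_matrix(net)
  ode <- assemble_odes(net, model, nm, divide_by_compartment = divide_by_compartment)
  vals <- resolve_values(model, nm)
  asg_constraints <- species_assignment_constraints(model, nm)

  dyn_idx <- dynamic_species_indices(net)
  S_dyn <- S[dyn_idx, , drop = FALSE]
  sp_ids <- vapply(net$species, `[[`, character(1), "id")
  dyn_vars <- unname(nm$species[sp_ids[dyn_idx]])
  basis <- left_kernel_basis(S_dyn)
  cons_constraints <- conservation_constraints(basis, vals$initial_values, dyn_vars)

  defic <- deficiency(net)
  ma <- is_mass_action(net, laws = ode$kinetic_laws, nm = nm)
  classification <- classify_vector_field(ode, c(asg_constraints, cons_constraints), ma)

  structure(
    list(
      model_id = model$model_id,
      network = net,
      ode = ode,
      stoichiometric = S,
      kinetic = K,
      parameter_values = vals$parameter_values,
      initial_values = vals$initial_values,
      constraints = c(asg_constraints, cons_constraints),
      conservation_basis = basis,
      dynamic_variables = dyn_vars,
      deficiency = defic,
      classification = classification,
      mass_action_per_reaction = ma$per_reaction,
      name_map = nm,
      provenance = list(
        source = source_name,
        tool = "sbml2ode",
        tool_version = as.character(utils::packageVersion("sbml2ode")),
        divide_by_compartment = divide_by_compartment
      )
    ),
    class = "ode_dataset"
  )
}

#' @export
print.ode_dataset <- function(x, ...) {
  cat(sprintf(
    "ode_dataset '%s': %d species, %d reactions, %d parameters\n",
    if (is.na(x$model_id)) x$provenance$source else x$model_id,
    length(x$network$species), length(x$network$reactions), length(x$network$parameters)
  ))
  cat(sprintf(
    "  deficiency %d (c = %d, l = %d, s = %d); %d conservation law(s)\n",
    x$deficiency$deficiency, x$deficiency$n_complexes,
    x$deficiency$n_linkage_classes, x$deficiency$rank,
    length(x$conservation_basis)
  ))
  cat(sprintf(
    "  vector field: %s; mass-action: %s; %s\n",
    x$classification$vector_field_class, x$classification$mass_action,
    if (x$ode$autonomous) "autonomous" else "non-autonomous"
  ))
  invisible(x)
}

#' @export
summary.ode_dataset <- function(object, ...) {
  print(object)
  cat("equations:\n")
  for (v in names(object$ode$equations)) {
    cat(sprintf("  d%s/dt = %s\n", v, ex_render(object$ode$equations[[v]], "plain")))
  }
  if (length(object$constraints)) {
    cat("constraints:\n")
    for (cn in object$constraints) {
      cat(sprintf(
        "  %s = %s   [%s]\n",
        ex_render(cn$lhs, "plain"), ex_render(cn$rhs, "plain"), cn$kind
      ))
    }
  }
  if (length(object$parameter_values)) {
    cat("parameter values:\n")
    for (k in names(object$parameter_values)) {
      cat(sprintf("  %s = %s\n", k, rq_to_str(object$parameter_values[[k]])))
    }
  }
  invisible(object)
}
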