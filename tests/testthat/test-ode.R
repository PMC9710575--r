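# ODE assembly: canonical naming, textbook assembly, SBML value semantics,
# constraints and numeric faithfulness of the symbolic right-hand sides.

pipeline <- function(doc, ...) sbml_to_ode(doc, ...)

test_that("canonical names follow document order with the stated parameter ordering", {
  ds <- pipeline(doc_local_shadow())
  nm <- ds$name_map
  expect_equal(unname(nm$species[c("A", "B")]), c("x1", "x2"))
  # global k first, then compartment c, then lifted locals in reaction order
  expect_equal(unname(nm$parameters["k"]), "k1")
  expect_equal(unname(nm$parameters["c"]), "k2")
  lifted <- setdiff(names(nm$parameters), c("k", "c"))
  expect_equal(unname(nm$parameters[lifted[grepl("^R1", lifted)]]), "k3")
  expect_equal(unname(nm$parameters[lifted[grepl("^R2", lifted)]]), "k4")
  # bijection round trip
  for (mathname in unname(nm$all)) {
    expect_equal(unname(nm$all[[nm$inv[[mathname]]]]), mathname)
  }
})

test_that("textbook mass-action assembly gives f1 = -k1*x1, f2 = k1*x1", {
  ds <- pipeline(doc_minimal())
  e_neg <- sbml2ode:::e_neg
  e_mul <- sbml2ode:::e_mul
  ex_sym <- sbml2ode:::ex_sym
  want <- e_mul(ex_sym("k1"), ex_sym("x1"))
  expect_true(sbml2ode:::ex_equal_sym(ds$ode$equations$x1, e_neg(want)))
  expect_true(sbml2ode:::ex_equal_sym(ds$ode$equations$x2, want))
  expect_true(ds$ode$autonomous)
  # every free symbol across equations is an x, a k, or t
  for (e in ds$ode$equations) {
    fr <- sbml2ode:::ex_free(e)$syms
    expect_true(all(grepl("^[xk][0-9]+$", fr)))
  }
})

test_that("boundary species get zero right-hand sides but keep their rows", {
  doc <- sub("<species id=\"A\" compartment=\"c\" initialConcentration=\"1\"/>",
             "<species id=\"A\" compartment=\"c\" initialConcentration=\"1\" boundaryCondition=\"true\"/>",
             doc_minimal(), fixed = TRUE)
  ds <- pipeline(doc)
  expect_true(sbml2ode:::ex_is_num(ds$ode$equations$x1, 0))
  expect_false(sbml2ode:::ex_is_num(ds$ode$equations$x2, 0))
  # S still reports the structural column including the boundary row
  expect_equal(rational_matrix_to_numeric(ds$stoichiometric), matrix(c(-1, 1), 2, 1))
})

test_that("species rate rules join the system and make it non-autonomous", {
  ds <- pipeline(doc_rate_rule_time())
  eq <- ds$ode$equations$x3
  expect_false(ds$ode$autonomous)
  expect_true(sbml2ode:::ex_free(eq)$time)
  # dC/dt = k2 * t with k2 renamed
  k2name <- unname(ds$name_map$parameters[["k2"]])
  expect_true(sbml2ode:::ex_equal_sym(
    eq, sbml2ode:::e_mul(sbml2ode:::ex_sym(k2name), sbml2ode:::ex_time())
  ))
})

test_that("compartment size divides rates and initial amounts", {
  ds <- pipeline(doc_compartment2())
  # f1 = -(k1*x1)/2; evaluate at x1 = 3, k1 = 0.1
  env <- c(x1 = 3, k1 = 0.1, k2 = 2)
  got <- sbml2ode:::ex_eval_num(ds$ode$equations$x1, env)
  expect_equal(got, -(0.1 * 3) / 2)
  # initial amount 4 over size 2 gives concentration 2
  expect_equal(rq_chr(ds$initial_values$x1), "2")
  # opting out of the division restores the amount-rate form
  ds2 <- pipeline(doc_compartment2(), divide_by_compartment = FALSE)
  got2 <- sbml2ode:::ex_eval_num(ds2$ode$equations$x1, env)
  expect_equal(got2, -(0.1 * 3))
})

test_that("value resolution honours SBML precedence and dependencies", {
  d <- doc_minimal()
  d <- sub("</listOfParameters>",
           "<parameter id=\"k2\" value=\"2\"/><parameter id=\"k3\" value=\"9\"/></listOfParameters>",
           d, fixed = TRUE)
  # initial assignment overrides the declared value: k2 := 3/2
  d <- sub("<listOfReactions>", paste0(
    "<listOfInitialAssignments><initialAssignment symbol=\"k2\">",
    math("<cn type=\"rational\">3<sep/>2</cn>"),
    "</initialAssignment></listOfInitialAssignments>\n",
    "<listOfRules><assignmentRule variable=\"k3\">",
    math("<apply><times/><cn type=\"integer\">2</cn><ci>k2</ci></apply>"),
    "</assignmentRule></listOfRules>\n<listOfReactions>"
  ), d, fixed = TRUE)
  ds <- pipeline(d)
  nm <- ds$name_map$parameters
  expect_equal(rq_chr(ds$parameter_values[[nm[["k2"]]]]), "3/2")
  # k3 := 2*k2 evaluated after k2's initial assignment: 3
  expect_equal(rq_chr(ds$parameter_values[[nm[["k3"]]]]), "3")
  expect_equal(rq_chr(ds$initial_values$x1), "1")
})

test_that("assignment-rule species become constraints, not equations", {
  ds <- pipeline(doc_assignment_species())
  # C (= x3) has no ODE; A and B do; every species has exactly one of the two
  expect_named(ds$ode$equations, c("x1", "x2"))
  asg <- Filter(function(cn) cn$kind == "species-assignment", ds$constraints)
  expect_length(asg, 1)
  expect_true(sbml2ode:::ex_equal_sym(asg[[1]]$lhs, sbml2ode:::ex_sym("x3")))
  expect_true(sbml2ode:::ex_equal_sym(
    asg[[1]]$rhs,
    sbml2ode:::ex_call("+", list(sbml2ode:::ex_sym("x1"), sbml2ode:::ex_sym("x2")))
  ))
  # the law k1*C was closed over true state variables: f depends on x1, x2 only
  fr <- sbml2ode:::ex_free(ds$ode$equations$x1)$syms
  expect_false("x3" %in% fr)
  expect_true(all(c("x1", "x2") %in% fr))
})

test_that("symbolic right-hand sides match independent floating evaluation", {
  set.seed(77)
  for (seed in 1:10) {
    fx <- generate_fixture(fixture_spec(2 + seed %% 4, 1 + seed %% 4,
      kinetics = c("mass-action", "mixed")[(seed %% 2) + 1],
      reversible_fraction = 0.4, seed = 500 + seed
    ))
    man <- fx$manifest
    ds <- sbml_to_ode(fx$sbml)
    nm <- ds$name_map
    n_sp <- length(man$species_ids)
    pvals <- vapply(man$param_values, as.numeric, numeric(1))
    for (pt in 1:5) {
      conc <- stats::setNames(sample(1:9, n_sp, replace = TRUE) / sample(1:4, n_sp, replace = TRUE),
                              man$species_ids)
      # oracle: plain floating evaluation of the generator's own laws via S
      rates <- vapply(man$laws, function(l) {
        sbml2ode:::ex_eval_num(l, c(as.list(conc), as.list(pvals)))
      }, numeric(1))
      f_oracle <- as.numeric(man$S %*% rates)
      env_math <- c(
        stats::setNames(as.list(conc), unname(nm$species[man$species_ids])),
        lapply(ds$parameter_values, sbml2ode:::rq_to_double)
      )
      dyn <- !man$boundary & !man$assignment_species
      for (i in which(dyn)) {
        xi <- unname(nm$species[[man$species_ids[i]]])
        got <- sbml2ode:::ex_eval_num(ds$ode$equations[[xi]], env_math)
        denom <- max(1, abs(f_oracle[i]))
        expect_lt(abs(got - f_oracle[i]) / denom, 1e-9)
      }
    }
  }
})
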