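# CRNT metrics: complexes, linkage classes, deficiency, and the kinetics
# classification.

net_of2 <- function(doc) {
  model <- parse_sbml(doc)
  model <- sbml2ode:::inline_model_functions(model)
  model <- lift_local_parameters(model)
  build_network(model)
}

test_that("complexes are exact multisets and arrows follow reversibility", {
  toys <- named_toys()
  en <- enumerate_complexes(net_of2(doc_minimal()))
  expect_length(en$complexes, 2)
  expect_equal(nrow(en$arrows), 1)

  # A + B <-> C shares complexes across directions: 2 complexes, 2 arrows
  en_b <- enumerate_complexes(net_of2(toys$bind$sbml))
  expect_length(en_b$complexes, 2)
  expect_equal(nrow(en_b$arrows), 2)

  # {A -> B, 2A -> 2B}: multiset distinctness gives 4 complexes
  en_d <- enumerate_complexes(net_of2(toys$def1$sbml))
  expect_length(en_d$complexes, 4)
  expect_equal(nrow(en_d$arrows), 2)

  # the zero complex models inflow/outflow
  en_i <- enumerate_complexes(net_of2(toys$inflow$sbml))
  expect_true("0" %in% names(en_i$complexes))
  expect_length(en_i$complexes, 2)
})

test_that("linkage classes are connected components of the complex graph", {
  toys <- named_toys()
  en_d <- enumerate_complexes(net_of2(toys$def1$sbml))
  expect_length(linkage_classes(en_d$complexes, en_d$arrows), 2)
  en_i <- enumerate_complexes(net_of2(toys$inflow$sbml))
  expect_length(linkage_classes(en_i$complexes, en_i$arrows), 1)
  expect_length(linkage_classes(list(), data.frame(from = character(0), to = character(0))), 0)
})

test_that("deficiency equals c - l - s on the canonical examples", {
  toys <- named_toys()
  d_min <- deficiency(net_of2(doc_minimal()))
  expect_equal(
    unlist(d_min[c("n_complexes", "n_linkage_classes", "rank", "deficiency")]),
    c(n_complexes = 2, n_linkage_classes = 1, rank = 1, deficiency = 0)
  )
  d_def1 <- deficiency(net_of2(toys$def1$sbml))
  expect_equal(
    unlist(d_def1[c("n_complexes", "n_linkage_classes", "rank", "deficiency")]),
    c(n_complexes = 4, n_linkage_classes = 2, rank = 1, deficiency = 1)
  )
  d_bind <- deficiency(net_of2(toys$bind$sbml))
  expect_equal(d_bind$deficiency, 0)
})

test_that("marking reactions reversible never changes c, l, s or deficiency", {
  for (seed in c(4, 18, 33, 47)) {
    fx <- generate_fixture(fixture_spec(4, 4, kinetics = "mass-action",
                                        reversible_fraction = 0, seed = seed))
    net <- net_of2(fx$sbml)
    d0 <- deficiency(net)
    net_rev <- net
    for (j in seq_along(net_rev$reactions)) net_rev$reactions[[j]]$reversible <- TRUE
    d1 <- deficiency(net_rev)
    expect_equal(
      unlist(d0[c("n_complexes", "n_linkage_classes", "rank", "deficiency")]),
      unlist(d1[c("n_complexes", "n_linkage_classes", "rank", "deficiency")])
    )
  }
})

test_that("the mass-action quotient test accepts constant factors only", {
  mk_net <- function(law_inner) {
    doc <- sub(math("<apply><times/><ci>k1</ci><ci>A</ci></apply>"),
               math(law_inner), doc_assignment_free_bind(), fixed = TRUE)
    net_of2(doc)
  }
  # local three-species helper document: A + B -> C with configurable law
  doc_assignment_free_bind <- function() {
    sbml_wrap(paste0(
      "<listOfCompartments><compartment id=\"c\" size=\"1\"/></listOfCompartments>\n",
      "<listOfSpecies>\n",
      "<species id=\"A\" compartment=\"c\" initialConcentration=\"1\"/>\n",
      "<species id=\"B\" compartment=\"c\" initialConcentration=\"1\"/>\n",
      "<species id=\"C\" compartment=\"c\" initialConcentration=\"0\"/>\n",
      "</listOfSpecies>\n",
      "<listOfParameters><parameter id=\"k1\" value=\"2\"/><parameter id=\"k2\" value=\"3\"/></listOfParameters>\n",
      "<listOfReactions>\n",
      "<reaction id=\"R1\" reversible=\"false\">\n",
      "<listOfReactants><speciesReference species=\"A\"/><speciesReference species=\"B\"/></listOfReactants>\n",
      "<listOfProducts><speciesReference species=\"C\"/></listOfProducts>\n",
      "<kineticLaw>", math("<apply><times/><ci>k1</ci><ci>A</ci></apply>"), "</kineticLaw>\n",
      "</reaction>\n</listOfReactions>\n"
    ))
  }
  # k1*A*B matches the reactant orders: pass
  ma1 <- is_mass_action(mk_net("<apply><times/><ci>k1</ci><ci>A</ci><ci>B</ci></apply>"))
  expect_true(ma1$model)
  # a parameter in the denominator is still a constant factor: pass
  ma2 <- is_mass_action(mk_net(
    "<apply><divide/><apply><times/><ci>k1</ci><ci>A</ci><ci>B</ci></apply><ci>k2</ci></apply>"
  ))
  expect_true(ma2$model)
  # a species-dependent quotient fails
  ma3 <- is_mass_action(mk_net(
    "<apply><divide/><apply><times/><ci>k1</ci><ci>A</ci></apply><apply><plus/><ci>k2</ci><ci>A</ci></apply></apply>"
  ))
  expect_false(ma3$model)
  # right orders but applied to the wrong species fails
  ma4 <- is_mass_action(mk_net("<apply><times/><ci>k1</ci><ci>A</ci><ci>C</ci></apply>"))
  expect_false(ma4$model)
})

test_that("generator labels are classified without error across 40 fixtures", {
  mis <- 0L
  for (seed in 1:40) {
    kin <- c("mass-action", "michaelis-menten", "mixed")[(seed %% 3) + 1]
    fx <- generate_fixture(fixture_spec(2 + seed %% 4, 1 + seed %% 5, kinetics = kin,
                                        reversible_fraction = 0.3, seed = 700 + seed))
    ds <- sbml_to_ode(fx$sbml)
    man <- fx$manifest
    if (isTRUE(ds$classification$mass_action) != man$expected_mass_action) mis <- mis + 1L
    if (ds$classification$vector_field_class != man$expected_vf_class) mis <- mis + 1L
    # invariant: mass_action implies polynomial
    if (isTRUE(ds$classification$mass_action)) {
      expect_equal(ds$classification$vector_field_class, "polynomial")
    }
  }
  expect_equal(mis, 0L)
})

test_that("a mass-action verdict reproduces the rates numerically", {
  # conservativeness: fitted constant * monomial equals the law at fresh points
  set.seed(3)
  for (seed in c(12, 25)) {
    fx <- generate_fixture(fixture_spec(4, 3, kinetics = "mass-action",
                                        reversible_fraction = 0, seed = seed))
    ds <- sbml_to_ode(fx$sbml)
    expect_true(ds$classification$mass_action)
    man <- fx$manifest
    nsp <- length(man$species_ids)
    pvals <- lapply(ds$parameter_values, sbml2ode:::rq_to_double)
    nm <- ds$name_map
    for (j in seq_along(man$laws)) {
      mono_val <- function(conc) prod(conc^man$K[seq_len(nrow(man$K)), j])
      law_val <- function(conc) {
        env <- c(stats::setNames(as.list(conc), unname(nm$species[man$species_ids])), pvals)
        sbml2ode:::ex_eval_num(ds$ode$kinetic_laws[[j]], env)
      }
      c0 <- stats::runif(nsp, 0.5, 2)
      fit <- law_val(c0) / mono_val(c0)
      for (rep in 1:4) {
        cx <- stats::runif(nsp, 0.5, 2)
        expect_equal(law_val(cx), fit * mono_val(cx), tolerance = 1e-9)
      }
    }
  }
})
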