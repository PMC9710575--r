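# SBML ingest: parsing fidelity, feature gating, local-parameter lifting.

test_that("parsing preserves every entity and its lexical numerals", {
  model <- parse_sbml(doc_minimal(k1_value = "1e-3"))
  expect_length(model$species, 2)
  expect_length(model$reactions, 1)
  expect_length(model$parameters, 1)
  expect_equal(model$parameters[[1]]$value_lex, "1e-3")
  expect_equal(model$species[[1]]$initial_concentration_lex, "1")
  # default stoichiometry is 1
  expect_equal(model$reactions[[1]]$reactants[[1]]$stoich_lex, "1")
  law <- model$reactions[[1]]$kinetic_law
  expect_true(sbml2ode:::ex_equal_sym(
    law, sbml2ode:::e_mul(sbml2ode:::ex_sym("k1"), sbml2ode:::ex_sym("A"))
  ))
})

test_that("entity counts match an independent XML count", {
  for (seed in c(3, 14, 27)) {
    fx <- generate_fixture(fixture_spec(4, 4, kinetics = "mixed",
                                        reversible_fraction = 0.5, seed = seed))
    model <- parse_sbml(fx$sbml)
    doc <- xml2::read_xml(fx$sbml)
    xml2::xml_ns_strip(doc)
    cnt <- function(xp) length(xml2::xml_find_all(doc, xp))
    expect_length(model$species, cnt("//listOfSpecies/species"))
    expect_length(model$reactions, cnt("//listOfReactions/reaction"))
    expect_length(model$parameters, cnt("//listOfParameters/parameter"))
    # generated ids round-trip exactly
    expect_identical(
      vapply(model$species, `[[`, character(1), "id"),
      fx$manifest$species_ids
    )
  }
})

test_that("malformed and unsupported documents are rejected at parse time", {
  expect_error(parse_sbml("<sbml level=\"2\"><model>"), "parse error")
  expect_error(parse_sbml("<foo/>"), "not an SBML")
  expect_error(parse_sbml(sub("level=\"2\"", "level=\"1\"", doc_minimal(), fixed = TRUE)),
               "Level 1")
})

test_that("feature gating enumerates every unsupported construct", {
  rep1 <- check_supported(parse_sbml(doc_minimal()))
  expect_true(rep1$supported)
  expect_equal(nrow(rep1$violations), 0)

  m_ev <- parse_sbml(doc_with_events())
  expect_true(m_ev$events_present)
  rep_ev <- check_supported(m_ev)
  expect_false(rep_ev$supported)
  expect_true("events" %in% rep_ev$violations$feature)

  rep_rr <- check_supported(parse_sbml(doc_param_rate_rule()))
  expect_false(rep_rr$supported)
  expect_true("parameter rate rule" %in% rep_rr$violations$feature)

  rep_irr <- check_supported(parse_sbml(doc_irrational_param()))
  expect_false(rep_irr$supported)
  expect_true("irrational parameter value" %in% rep_irr$violations$feature)
  expect_true("p" %in% rep_irr$violations$id)
})

test_that("local parameters lift to fresh globals respecting SBML scoping", {
  model <- parse_sbml(doc_local_shadow())
  lifted <- lift_local_parameters(model)
  ids <- sbml2ode:::model_parameter_ids(lifted)
  # global k survives; each reaction's local k becomes its own global
  expect_true("k" %in% ids)
  expect_length(ids, 3)
  expect_length(unique(ids), 3)
  # R1's law references R1's lifted local, not the global k
  law1 <- lifted$reactions[[1]]$kinetic_law
  fr1 <- sbml2ode:::ex_free(law1)$syms
  expect_false("k" %in% fr1)
  expect_true(any(grepl("^R1", fr1)))
  law2 <- lifted$reactions[[2]]$kinetic_law
  expect_true(any(grepl("^R2", sbml2ode:::ex_free(law2)$syms)))
  # idempotence and identity on local-free models
  expect_identical(lift_local_parameters(lifted), lifted)
  plain <- parse_sbml(doc_minimal())
  expect_identical(lift_local_parameters(plain), plain)
})

test_that("models passing the gate run the full pipeline without error", {
  for (seed in 1:15) {
    fx <- generate_fixture(fixture_spec(2 + seed %% 4, 1 + seed %% 5,
      kinetics = c("mass-action", "michaelis-menten", "mixed")[(seed %% 3) + 1],
      reversible_fraction = 0.4,
      include_boundary = seed %% 4 == 0,
      include_rules = seed %% 5 == 0,
      seed = 1000 + seed
    ))
    expect_true(check_supported(parse_sbml(fx$sbml))$supported)
    expect_s3_class(sbml_to_ode(fx$sbml), "ode_dataset")
  }
})
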