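# Linear conservation laws: exactness, completeness, dynamic consistency.

test_that("canonical toy networks yield the expected conservation bases", {
  toys <- named_toys()
  ds_iso <- sbml_to_ode(toys$iso$sbml)
  expect_length(ds_iso$conservation_basis, 1)
  expect_equal(ds_iso$conservation_basis[[1]], c(1, 1))
  # conserved total from exact initial values: 2 + 1/2 = 5/2
  cons <- Filter(function(cn) cn$kind == "conservation", ds_iso$constraints)
  expect_equal(rq_chr(cons[[1]]$total), "5/2")

  ds_bind <- sbml_to_ode(toys$bind$sbml)
  expect_length(ds_bind$conservation_basis, 2)
  # span check: every basis vector lies in span{(1,0,1),(0,1,1)} and spans it
  want <- rbind(c(1, 0, 1), c(0, 1, 1))
  got <- do.call(rbind, ds_bind$conservation_basis)
  expect_identical(helper_int_rank(rbind(want, got)), 2L)
  expect_identical(helper_int_rank(got), 2L)

  ds_in <- sbml_to_ode(toys$inflow$sbml)
  expect_length(ds_in$conservation_basis, 0)
})

test_that("a symbolic total is issued when initial values are missing", {
  d <- doc_minimal()
  d <- sub(" initialConcentration=\"0\"", "", d, fixed = TRUE)
  ds <- sbml_to_ode(d)
  cons <- Filter(function(cn) cn$kind == "conservation", ds$constraints)
  expect_length(cons, 1)
  expect_null(cons[[1]]$total)
  expect_equal(cons[[1]]$rhs$t, "sym")
  expect_match(cons[[1]]$rhs$name, "^c[0-9]+$")
})

test_that("basis vectors annihilate S_dyn exactly and count to n_dyn - rank", {
  for (seed in 1:20) {
    fx <- generate_fixture(fixture_spec(2 + seed %% 5, 1 + seed %% 6,
      kinetics = "mass-action", reversible_fraction = 0.3,
      include_boundary = seed %% 4 == 0, seed = 200 + seed
    ))
    ds <- sbml_to_ode(fx$sbml)
    S <- ds$stoichiometric
    man <- fx$manifest
    dyn <- which(!man$boundary & !man$assignment_species)
    S_dyn <- S[dyn, , drop = FALSE]
    basis <- ds$conservation_basis
    expect_length(basis, length(dyn) - helper_int_rank(man$S[dyn, , drop = FALSE]))
    for (y in basis) {
      expect_true(all(y == floor(y)))
      expect_true(any(y != 0))
      # primitive: gcd of |entries| is 1
      g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), c(abs(y[y != 0]), 0))
      expect_equal(g, 1)
      for (j in seq_len(ncol(S_dyn))) {
        dot <- sbml2ode:::rq_sum(lapply(seq_along(dyn), function(i) {
          sbml2ode:::rq_mul(sbml2ode:::rq_int(y[i]), S_dyn[[i, j]])
        }))
        expect_true(sbml2ode:::rq_is_zero(dot))
      }
    }
    # linear independence of the returned basis
    if (length(basis)) {
      expect_identical(helper_int_rank(do.call(rbind, basis)), length(basis))
    }
  }
})

test_that("conserved totals differentiate to symbolic zero on mass-action models", {
  for (seed in c(31, 44, 59)) {
    fx <- generate_fixture(fixture_spec(4, 3, kinetics = "mass-action",
                                        reversible_fraction = 0.5, seed = seed))
    ds <- sbml_to_ode(fx$sbml)
    dyn_vars <- ds$dynamic_variables
    for (y in ds$conservation_basis) {
      terms <- list()
      for (i in seq_along(y)) {
        if (y[i] == 0) next
        terms[[length(terms) + 1L]] <- sbml2ode:::e_mul(
          sbml2ode:::ex_num(y[i]), ds$ode$equations[[dyn_vars[i]]]
        )
      }
      if (!length(terms)) next
      p <- sbml2ode:::ex_poly(sbml2ode:::e_sum(terms))
      expect_false(is.null(p))
      expect_true(sbml2ode:::poly_is_zero(p))
    }
  }
})

test_that("kernel span matches a brute-force nullspace on random matrices", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(2:8, 1); r <- sample(1:8, 1)
    A <- matrix(sample(-2:2, n * r, replace = TRUE), n, r)
    basis <- left_kernel_basis(sbml2ode:::rmat_from_num(A))
    k_want <- n - helper_int_rank(A)
    expect_length(basis, k_want)
    for (y in basis) expect_true(all(y %*% A == 0))
    if (length(basis)) {
      expect_identical(helper_int_rank(do.call(rbind, basis)), k_want)
    }
  }
})
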