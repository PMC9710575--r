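# Exact rational arithmetic: lexical and binary conversions, closure under
# field operations, and the exact linear algebra built on top.

test_that("decimal text converts to the exact rational it denotes", {
  expect_equal(rq_chr(literal_to_rational("0.5")), "1/2")
  expect_equal(rq_chr(literal_to_rational("1e-3")), "1/1000")
  expect_equal(rq_chr(literal_to_rational("3.14159")), "314159/100000")
  expect_equal(rq_chr(literal_to_rational("-0.25")), "-1/4")
  expect_equal(rq_chr(literal_to_rational("2.5e2")), "250")
  expect_equal(rq_chr(literal_to_rational("7")), "7")
  expect_equal(rq_chr(literal_to_rational("0.000")), "0")
  expect_error(literal_to_rational(""), "invalid")
  expect_error(literal_to_rational("NaN"), "invalid")
  expect_error(literal_to_rational("INF"), "invalid")
  expect_error(literal_to_rational("1.2.3"), "invalid")
})

test_that("doubles convert to their exact binary rational", {
  expect_equal(rq_chr(double_to_rational(0.25)), "1/4")
  expect_equal(rq_chr(double_to_rational(-2)), "-2")
  # the double nearest 0.1 is exactly 3602879701896397 / 2^55
  expect_equal(
    rq_chr(double_to_rational(0.1)),
    "3602879701896397/36028797018963968"
  )
  expect_error(double_to_rational(NaN), "invalid")
  expect_error(double_to_rational(Inf), "invalid")
})

test_that("rational arithmetic is exact, not approximate", {
  rq_int <- sbml2ode:::rq_int
  third <- sbml2ode:::rq_div(rq_int(1), rq_int(3))
  expect_equal(rq_chr(sbml2ode:::rq_mul(third, rq_int(3))), "1")
  s <- sbml2ode:::rq_add(literal_to_rational("0.5"), third)
  expect_equal(rq_chr(s), "5/6")
  # round trip: parse -> print -> parse is the identity on the value
  for (lex in c("0.1", "12.345", "-7e-2", "1234567890123456789", "0.0625")) {
    q <- literal_to_rational(lex)
    back <- eval_constant(sbml2ode:::sage_parse_expr(rq_chr(q)), list())
    expect_false(back$irrational)
    expect_true(sbml2ode:::rq_eq(q, back$value))
  }
})

test_that("random rational arithmetic agrees with floating point", {
  set.seed(41)
  rq_int <- sbml2ode:::rq_int
  for (i in 1:200) {
    a <- rq_int(sample(-50:50, 1))
    b <- rq_int(sample(1:50, 1))
    cd <- sample(1:50, 2)
    x <- sbml2ode:::rq_div(a, b)
    y <- sbml2ode:::rq_div(rq_int(cd[1]), rq_int(cd[2]))
    got <- switch(sample(3, 1),
      sbml2ode:::rq_add(x, y),
      sbml2ode:::rq_mul(x, y),
      sbml2ode:::rq_sub(x, y)
    )
    ref <- c(
      sbml2ode:::rq_to_double(x) + sbml2ode:::rq_to_double(y),
      sbml2ode:::rq_to_double(x) * sbml2ode:::rq_to_double(y),
      sbml2ode:::rq_to_double(x) - sbml2ode:::rq_to_double(y)
    )
    expect_true(any(abs(sbml2ode:::rq_to_double(got) - ref) < 1e-12))
  }
})

test_that("big integer division and gcd satisfy their defining identities", {
  set.seed(7)
  bi_from_str <- sbml2ode:::bi_from_str
  for (i in 1:30) {
    a <- bi_from_str(paste(sample(0:9, sample(5:25, 1), replace = TRUE), collapse = ""))
    b <- bi_from_str(paste(c(sample(1:9, 1), sample(0:9, sample(1:12, 1), replace = TRUE)), collapse = ""))
    dm <- sbml2ode:::mag_divmod(a$m, b$m)
    recon <- sbml2ode:::bi_add(
      sbml2ode:::bi_mul(sbml2ode:::bi_new(1L, dm$q), b),
      sbml2ode:::bi_new(if (length(dm$r)) 1L else 0L, dm$r)
    )
    expect_true(sbml2ode:::bi_eq(sbml2ode:::bi_abs(a), recon))
    expect_true(sbml2ode:::mag_cmp(dm$r, b$m) < 0)
    g <- sbml2ode:::bi_gcd(a, b)
    expect_true(sbml2ode:::bi_is_zero(
      sbml2ode:::bi_sub(a, sbml2ode:::bi_mul(sbml2ode:::bi_div_exact(a, g), g))
    ))
  }
})

test_that("constant expressions evaluate exactly and flag irrationals", {
  rq_int <- sbml2ode:::rq_int
  # (1/2 + 1/3) * 6 = 5
  e <- sbml2ode:::e_mul(
    sbml2ode:::ex_call("+", list(
      sbml2ode:::ex_num(sbml2ode:::rq_div(rq_int(1), rq_int(2))),
      sbml2ode:::ex_num(sbml2ode:::rq_div(rq_int(1), rq_int(3)))
    )),
    sbml2ode:::ex_num(6)
  )
  r <- eval_constant(e, list())
  expect_false(r$irrational)
  expect_equal(rq_chr(r$value), "5")

  expect_false(eval_constant(read_math_ex("<apply><exp/><cn type=\"integer\">0</cn></apply>"))$irrational)
  expect_true(eval_constant(read_math_ex("<apply><exp/><cn type=\"integer\">1</cn></apply>"))$irrational)
  # 4^(1/2) = 2 exactly; 2^(1/2) is irrational
  expect_equal(rq_chr(eval_constant(read_math_ex(
    "<apply><power/><cn type=\"integer\">4</cn><cn type=\"rational\">1<sep/>2</cn></apply>"
  ))$value), "2")
  expect_true(eval_constant(read_math_ex(
    "<apply><power/><cn type=\"integer\">2</cn><cn type=\"rational\">1<sep/>2</cn></apply>"
  ))$irrational)
  expect_true(eval_constant(read_math_ex("<pi/>"))$irrational)
  expect_error(eval_constant(read_math_ex(
    "<apply><divide/><cn type=\"integer\">1</cn><cn type=\"integer\">0</cn></apply>"
  )), "zero")
})

test_that("exact matrix rank agrees with an independent elimination", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    r <- sample(1:8, 1)
    A <- matrix(sample(-3:3, n * r, replace = TRUE), n, r)
    M <- sbml2ode:::rmat_from_num(A)
    expect_identical(sbml2ode:::rmat_rank(M), helper_int_rank(A))
  }
})

test_that("rational nullspace vectors annihilate the matrix exactly", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    r <- sample(1:6, 1)
    A <- matrix(sample(-2:2, n * r, replace = TRUE), n, r)
    M <- sbml2ode:::rmat_from_num(A)
    ns <- sbml2ode:::rmat_nullspace(M)
    expect_length(ns, ncol(A) - helper_int_rank(A))
    for (v in ns) {
      for (row in seq_len(n)) {
        dot <- sbml2ode:::rq_dot(lapply(seq_len(r), function(j) M[[row, j]]), v)
        expect_true(sbml2ode:::rq_is_zero(dot))
      }
    }
  }
})
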