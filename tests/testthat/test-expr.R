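# Expression trees: MathML reading, function inlining, classification,
# monomial decomposition and dialect rendering.

test_that("MathML content markup parses to the expected trees", {
  e <- read_math_ex("<apply><times/><ci>k1</ci><ci>A</ci></apply>")
  expect_equal(e$t, "call")
  expect_equal(e$op, "*")
  expect_equal(vapply(e$args, `[[`, character(1), "name"), c("k1", "A"))

  # cn flavours: real keeps the lexical string, e-notation and rational are exact
  expect_equal(read_math_ex("<cn>0.5</cn>")$lex, "0.5")
  expect_equal(rq_chr(read_math_ex("<cn type=\"e-notation\">1<sep/>-3</cn>")$q), "1/1000")
  expect_equal(rq_chr(read_math_ex("<cn type=\"rational\">2<sep/>6</cn>")$q), "1/3")

  tm <- read_math_ex(paste0(
    "<csymbol encoding=\"text\" definitionURL=\"http://www.sbml.org/sbml/symbols/time\">t</csymbol>"
  ))
  expect_equal(tm$t, "time")

  # unary vs binary minus
  expect_equal(read_math_ex("<apply><minus/><ci>x</ci></apply>")$op, "neg")
  expect_equal(read_math_ex("<apply><minus/><ci>x</ci><ci>y</ci></apply>")$op, "-")

  # unsupported constructs are carried as unknown heads, not errors
  pw <- read_math_ex("<piecewise><piece><cn>1</cn><ci>x</ci></piece></piecewise>")
  expect_true(startsWith(pw$op, "unknown:"))
})

test_that("function definitions inline fully, nested and capture-free", {
  ex_sym <- sbml2ode:::ex_sym
  defs <- list(
    f = list(args = c("a", "b"), body = read_math_ex("<apply><times/><ci>a</ci><ci>b</ci></apply>"))
  )
  out <- inline_function_definitions(
    sbml2ode:::ex_funcall("f", list(ex_sym("k1"), ex_sym("x1"))), defs
  )
  expect_true(sbml2ode:::ex_equal_sym(out, sbml2ode:::e_mul(ex_sym("k1"), ex_sym("x1"))))

  # nested: f(a) = g(a) + 1, g(a) = 2a  =>  f(x1) = 2*x1 + 1
  defs2 <- list(
    f = list(args = "a", body = read_math_ex(
      "<apply><plus/><apply><ci>g</ci><ci>a</ci></apply><cn type=\"integer\">1</cn></apply>"
    )),
    g = list(args = "a", body = read_math_ex(
      "<apply><times/><cn type=\"integer\">2</cn><ci>a</ci></apply>"
    ))
  )
  out2 <- inline_function_definitions(sbml2ode:::ex_funcall("f", list(ex_sym("x1"))), defs2)
  want <- read_math_ex(
    "<apply><plus/><apply><times/><cn type=\"integer\">2</cn><ci>x1</ci></apply><cn type=\"integer\">1</cn></apply>"
  )
  expect_true(sbml2ode:::ex_equal_sym(out2, want))
  expect_length(sbml2ode:::ex_funcall_names(out2), 0)

  # swapped arguments must not capture each other
  defs3 <- list(
    h = list(args = c("a", "b"), body = read_math_ex("<apply><divide/><ci>a</ci><ci>b</ci></apply>"))
  )
  out3 <- inline_function_definitions(
    sbml2ode:::ex_funcall("h", list(ex_sym("b"), ex_sym("a"))), defs3
  )
  expect_true(sbml2ode:::ex_equal_sym(out3, sbml2ode:::e_div(ex_sym("b"), ex_sym("a"))))

  # self-recursion is a cycle error; wrong arity is an arity error
  defsr <- list(f = list(args = "a", body = sbml2ode:::ex_funcall("f", list(ex_sym("a")))))
  expect_error(
    inline_function_definitions(sbml2ode:::ex_funcall("f", list(ex_sym("x1"))), defsr),
    "recursive"
  )
  expect_error(
    inline_function_definitions(sbml2ode:::ex_funcall("f", list(ex_sym("x1"), ex_sym("x2"))), defs2),
    "arity"
  )
})

test_that("vector-field expressions classify as polynomial/rational/other", {
  cls <- function(inner) {
    sbml2ode:::classify_expr(read_math_ex(inner), c("x1", "x2", "x3"))
  }
  expect_equal(cls(paste0(
    "<apply><minus/><apply><times/><ci>k1</ci><ci>x1</ci><ci>x2</ci></apply>",
    "<apply><times/><ci>k2</ci><ci>x3</ci></apply></apply>"
  )), "polynomial")
  expect_equal(cls(paste0(
    "<apply><divide/><apply><times/><ci>k1</ci><ci>x1</ci></apply>",
    "<apply><plus/><ci>k2</ci><ci>x1</ci></apply></apply>"
  )), "rational")
  expect_equal(cls("<apply><exp/><ci>x1</ci></apply>"), "other")
  # dividing by a parameter-only expression keeps a polynomial polynomial
  expect_equal(cls(paste0(
    "<apply><divide/><apply><times/><ci>k1</ci><ci>x1</ci></apply><ci>k2</ci></apply>"
  )), "polynomial")
})

test_that("generalized monomials decompose against a species set", {
  mono <- function(inner) sbml2ode:::ex_monomial(read_math_ex(inner), c("x1", "x2", "x3"))
  m <- mono("<apply><times/><ci>k1</ci><ci>x1</ci><ci>x2</ci></apply>")
  expect_equal(sort(names(m)), c("x1", "x2"))
  expect_equal(unname(m[c("x1", "x2")]), c(1, 1))
  # constant factor may contain parameters through division
  m2 <- mono("<apply><divide/><apply><times/><ci>k1</ci><ci>x1</ci><ci>x2</ci></apply><ci>k2</ci></apply>")
  expect_equal(unname(m2[c("x1", "x2")]), c(1, 1))
  m3 <- mono("<apply><times/><ci>k1</ci><apply><power/><ci>x1</ci><cn type=\"integer\">2</cn></apply></apply>")
  expect_equal(unname(m3["x1"]), 2)
  # Michaelis-Menten does not decompose
  expect_null(mono(paste0(
    "<apply><divide/><apply><times/><ci>k1</ci><ci>x1</ci></apply>",
    "<apply><plus/><ci>k2</ci><ci>x1</ci></apply></apply>"
  )))
})

test_that("polynomial expansion detects symbolic zeros", {
  # k*(x+y) - k*x - k*y == 0
  e <- read_math_ex(paste0(
    "<apply><minus/>",
    "<apply><minus/>",
    "<apply><times/><ci>k</ci><apply><plus/><ci>x</ci><ci>y</ci></apply></apply>",
    "<apply><times/><ci>k</ci><ci>x</ci></apply></apply>",
    "<apply><times/><ci>k</ci><ci>y</ci></apply></apply>"
  ))
  p <- sbml2ode:::ex_poly(e)
  expect_false(is.null(p))
  expect_true(sbml2ode:::poly_is_zero(p))
  # a rational function is not a polynomial
  expect_null(sbml2ode:::ex_poly(read_math_ex(
    "<apply><divide/><ci>x</ci><apply><plus/><ci>k</ci><ci>x</ci></apply></apply>"
  )))
})

test_that("rendered expressions parse back to equal expressions", {
  exprs <- list(
    read_math_ex("<apply><times/><ci>k1</ci><ci>x1</ci></apply>"),
    read_math_ex(paste0(
      "<apply><minus/><apply><times/><ci>k1</ci><ci>x1</ci><ci>x2</ci></apply>",
      "<apply><times/><ci>k2</ci><ci>x3</ci></apply></apply>"
    )),
    read_math_ex(paste0(
      "<apply><divide/><apply><times/><ci>k1</ci><ci>x1</ci></apply>",
      "<apply><plus/><ci>k2</ci><ci>x1</ci></apply></apply>"
    )),
    sbml2ode:::e_mul(
      sbml2ode:::ex_num(sbml2ode:::rq_div(sbml2ode:::rq_int(-3), sbml2ode:::rq_int(7))),
      sbml2ode:::e_pow(sbml2ode:::ex_sym("x2"), sbml2ode:::ex_num(3))
    )
  )
  for (e in exprs) {
    txt <- sbml2ode:::ex_render(e, "sagemath")
    expect_false(grepl("[0-9]\\.[0-9]", txt))
    back <- sbml2ode:::sage_parse_expr(txt)
    expect_true(sbml2ode:::ex_equal_sym(back, e))
  }
  # LaTeX renders rationals as \frac
  q <- sbml2ode:::ex_num(sbml2ode:::rq_div(sbml2ode:::rq_int(1), sbml2ode:::rq_int(10)))
  expect_match(sbml2ode:::ex_render(q, "latex"), "\\\\frac\\{1\\}\\{10\\}")
})
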