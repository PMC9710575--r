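# Symbolic expression trees.
#
# Nodes are tagged lists of class "sbex":
#   list(t = "num",  q = rq, lex = optional lexical string)
#   list(t = "sym",  name = chr)
#   list(t = "time")                      -- the reserved time symbol t
#   list(t = "call", op = chr, args = list of nodes)
#   list(t = "funcall", fn = chr, args = list of nodes)  -- user functions,
#                                            removed by inlining
# Builtin ops: "+" (n-ary), "-" (binary), "neg", "*" (n-ary), "/", "^",
# "exp", "ln", "log" (args: base, argument), "sin", "cos", "tan", "abs",
# "pi", "ee" (Euler's number).  Anything else is carried as "unknown:<head>"
# and rejected by feature gating before it can reach the ODE layer.

ex_num <- function(q, lex = NULL) {
  if (is.numeric(q)) q <- rq_int(q)
  structure(list(t = "num", q = q, lex = lex), class = "sbex")
}
ex_sym <- function(name) structure(list(t = "sym", name = name), class = "sbex")
ex_time <- function() structure(list(t = "time"), class = "sbex")
ex_call <- function(op, args) structure(list(t = "call", op = op, args = args), class = "sbex")
ex_funcall <- function(fn, args) structure(list(t = "funcall", fn = fn, args = args), class = "sbex")

e_add <- function(...) ex_call("+", list(...))
e_sum <- function(args) {
  if (length(args) == 0) return(ex_num(rq_zero()))
  if (length(args) == 1) return(args[[1]])
  ex_call("+", args)
}
e_sub <- function(a, b) ex_call("-", list(a, b))
e_neg <- function(a) ex_call("neg", list(a))
e_mul <- function(...) ex_call("*", list(...))
e_prod <- function(args) {
  if (length(args) == 0) return(ex_num(rq_one()))
  if (length(args) == 1) return(args[[1]])
  ex_call("*", args)
}
e_div <- function(a, b) ex_call("/", list(a, b))
e_pow <- function(a, b) ex_call("^", list(a, b))

is_ex <- function(x) inherits(x, "sbex")

ex_is_num <- function(e, val = NULL) {
  if (e$t != "num") return(FALSE)
  if (is.null(val)) return(TRUE)
  rq_eq(e$q, rq_int(val))
}

# ---- traversal helpers ----

ex_children <- function(e) if (e$t %in% c("call", "funcall")) e$args else list()

ex_map_children <- function(e, f) {
  if (e$t %in% c("call", "funcall")) e$args <- lapply(e$args, f)
  e
}

# free symbol names and whether the time symbol occurs
ex_free <- function(e) {
  syms <- character(0)
  uses_time <- FALSE
  walk <- function(x) {
    if (x$t == "sym") {
      syms[[length(syms) + 1L]] <<- x$name
    } else if (x$t == "time") {
      uses_time <<- TRUE
    } else {
      for (a in ex_children(x)) walk(a)
    }
  }
  walk(e)
  list(syms = unique(syms), time = uses_time)
}

ex_uses_any <- function(e, names, or_time = FALSE) {
  fr <- ex_free(e)
  (or_time && fr$time) || any(fr$syms %in% names)
}

# simultaneous symbol -> expression substitution (capture is impossible in
# this binder-free language once lambdas are inlined away)
ex_subst <- function(e, env) {
  if (e$t == "sym" && !is.null(env[[e$name]])) return(env[[e$name]])
  ex_map_children(e, function(a) ex_subst(a, env))
}

# symbol -> symbol renaming via a named character map
ex_rename <- function(e, map) {
  if (e$t == "sym" && e$name %in% names(map)) return(ex_sym(unname(map[[e$name]])))
  ex_map_children(e, function(a) ex_rename(a, map))
}

ex_unknown_heads <- function(e) {
  out <- character(0)
  walk <- function(x) {
    if (x$t == "call" && startsWith(x$op, "unknown:")) {
      out[[length(out) + 1L]] <<- sub("^unknown:", "", x$op)
    }
    for (a in ex_children(x)) walk(a)
  }
  walk(e)
  unique(out)
}

ex_funcall_names <- function(e) {
  out <- character(0)
  walk <- function(x) {
    if (x$t == "funcall") out[[length(out) + 1L]] <<- x$fn
    for (a in ex_children(x)) walk(a)
  }
  walk(e)
  unique(out)
}

# ---- MathML (content markup) -> expression tree ----

.mathml_head_map <- c(
  plus = "+", times = "*", divide = "/", power = "^",
  exp = "exp", ln = "ln", sin = "sin", cos = "cos", tan = "tan", abs = "abs"
)

mathml_to_ex <- function(node) {
  name <- xml2::xml_name(node)
  if (name %in% c("math", "semantics")) {
    kids <- xml2::xml_children(node)
    kids <- kids[!(xml2::xml_name(kids) %in% c("annotation", "annotation-xml"))]
    if (length(kids) != 1) stop("malformed MathML: expected a single child of <", name, ">")
    return(mathml_to_ex(kids[[1]]))
  }
  switch(name,
    ci = ex_sym(trimws(xml2::xml_text(node))),
    cn = mathml_cn_to_ex(node),
    csymbol = mathml_csymbol_to_ex(node),
    apply = mathml_apply_to_ex(node),
    pi = ex_call("pi", list()),
    exponentiale = ex_call("ee", list()),
    infinity = ex_call("unknown:infinity", list()),
    notanumber = ex_call("unknown:notanumber", list()),
    piecewise = ex_call("unknown:piecewise", lapply(xml2::xml_children(node), function(x) ex_num(0))),
    ex_call(paste0("unknown:", name), list())
  )
}

mathml_cn_to_ex <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (is.na(type)) type <- "real"
  txt_parts <- function() {
    kids <- xml2::xml_contents(node)
    parts <- character(0)
    cur <- ""
    for (k in kids) {
      if (xml2::xml_name(k) == "sep") {
        parts <- c(parts, cur)
        cur <- ""
      } else {
        cur <- paste0(cur, xml2::xml_text(k))
      }
    }
    c(parts, cur)
  }
  if (type %in% c("real", "integer")) {
    lex <- trimws(xml2::xml_text(node))
    return(ex_num(literal_to_rational(lex), lex = lex))
  }
  if (type == "e-notation") {
    p <- trimws(txt_parts())
    lex <- paste0(p[1], "e", p[2])
    return(ex_num(literal_to_rational(lex), lex = lex))
  }
  if (type == "rational") {
    p <- trimws(txt_parts())
    return(ex_num(rq_div(literal_to_rational(p[1]), literal_to_rational(p[2]))))
  }
  ex_call(paste0("unknown:cn-", type), list())
}

mathml_csymbol_to_ex <- function(node) {
  url <- xml2::xml_attr(node, "definitionURL")
  if (!is.na(url) && grepl("time", url)) return(ex_time())
  if (!is.na(url) && grepl("avogadro", url)) {
    return(ex_num(literal_to_rational("6.02214179e23")))
  }
  if (!is.na(url) && grepl("delay", url)) return(ex_call("unknown:delay", list()))
  ex_call(paste0("unknown:csymbol"), list())
}

mathml_apply_to_ex <- function(node) {
  kids <- xml2::xml_children(node)
  if (length(kids) == 0) stop("malformed MathML: empty <apply>")
  head <- kids[[1]]
  hname <- xml2::xml_name(head)
  rest <- kids[-1]
  if (hname == "ci") {
    return(ex_funcall(trimws(xml2::xml_text(head)), lapply(rest, mathml_to_ex)))
  }
  if (hname == "minus") {
    args <- lapply(rest, mathml_to_ex)
    if (length(args) == 1) return(e_neg(args[[1]]))
    if (length(args) == 2) return(e_sub(args[[1]], args[[2]]))
    stop("malformed MathML: <minus> with ", length(args), " arguments")
  }
  if (hname == "root") {
    degree <- 2
    deg_idx <- which(xml2::xml_name(rest) == "degree")
    if (length(deg_idx)) {
      dex <- mathml_to_ex(xml2::xml_child(rest[[deg_idx]]))
      rest <- rest[-deg_idx]
      if (dex$t == "num" && rq_is_int(dex$q)) {
        degree <- rq_to_double(dex$q)
      } else {
        return(ex_call("unknown:root", list()))
      }
    }
    arg <- mathml_to_ex(rest[[1]])
    return(e_pow(arg, ex_num(rq_div(rq_one(), rq_int(degree)))))
  }
  if (hname == "log") {
    base <- ex_num(10)
    base_idx <- which(xml2::xml_name(rest) == "logbase")
    if (length(base_idx)) {
      base <- mathml_to_ex(xml2::xml_child(rest[[base_idx]]))
      rest <- rest[-base_idx]
    }
    return(ex_call("log", list(base, mathml_to_ex(rest[[1]]))))
  }
  args <- lapply(rest, mathml_to_ex)
  if (hname %in% names(.mathml_head_map)) {
    op <- .mathml_head_map[[hname]]
    if (op %in% c("/", "^") && length(args) != 2) {
      stop("malformed MathML: <", hname, "> expects 2 arguments")
    }
    if (op == "+" && length(args) == 0) return(ex_num(0))
    if (op == "*" && length(args) == 0) return(ex_num(1))
    if (length(args) == 1 && op %in% c("+", "*")) return(args[[1]])
    return(ex_call(op, args))
  }
  ex_call(paste0("unknown:", hname), args)
}

# ---- expression tree -> MathML (used by the fixture generator) ----

ex_to_mathml <- function(e) {
  render <- function(x) {
    switch(x$t,
      num = {
        q <- x$q
        if (rq_is_int(q)) {
          sprintf("<cn type=\"integer\"> %s </cn>", bi_to_str(q$n))
        } else {
          sprintf("<cn type=\"rational\"> %s <sep/> %s </cn>", bi_to_str(q$n), bi_to_str(q$d))
        }
      },
      sym = sprintf("<ci> %s </ci>", x$name),
      time = "<csymbol encoding=\"text\" definitionURL=\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>",
      call = {
        head <- switch(x$op,
          "+" = "plus", "-" = "minus", "neg" = "minus", "*" = "times",
          "/" = "divide", "^" = "power",
          exp = "exp", ln = "ln", sin = "sin", cos = "cos", tan = "tan", abs = "abs",
          stop("cannot serialize op to MathML: ", x$op)
        )
        paste0(
          "<apply> <", head, "/> ",
          paste(vapply(x$args, render, character(1)), collapse = " "),
          " </apply>"
        )
      },
      stop("cannot serialize node to MathML: ", x$t)
    )
  }
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\"> ", render(e), " </math>")
}

# ---- function-definition inlining ----

#' Inline SBML function definitions into an expression
#'
#' Replaces every call to a user-defined function by its body with the formal
#' arguments simultaneously substituted by the (already inlined) actual
#' arguments; nested definitions are fully expanded. Simultaneous
#' substitution in this binder-free expression language makes the operation
#' capture-avoiding.
#'
#' @param expr an expression tree as produced by the SBML parser.
#' @param defs a named list of definitions, each `list(args = <character>,
#'   body = <expression>)`.
#' @return an expression tree free of function-call nodes.
#' @export
inline_function_definitions <- function(expr, defs) {
  # cycle detection on the call graph of the definitions
  graph <- lapply(defs, function(d) intersect(ex_funcall_names(d$body), names(defs)))
  state <- new.env(parent = emptyenv())
  visit <- function(f, stack) {
    if (f %in% stack) stop("recursive function definitions: ", paste(c(stack, f), collapse = " -> "))
    if (isTRUE(state[[f]])) return(invisible())
    for (g in graph[[f]]) visit(g, c(stack, f))
    state[[f]] <- TRUE
  }
  for (f in names(defs)) visit(f, character(0))

  inline <- function(x) {
    if (x$t == "funcall") {
      d <- defs[[x$fn]]
      if (is.null(d)) stop("call to undefined function: ", x$fn)
      if (length(d$args) != length(x$args)) {
        stop("arity mismatch in call to ", x$fn, ": expected ", length(d$args),
             " arguments, got ", length(x$args))
      }
      args <- lapply(x$args, inline)
      env <- stats::setNames(args, d$args)
      return(ex_subst(inline(d$body), env))
    }
    ex_map_children(x, inline)
  }
  inline(expr)
}

# ---- numeric (double) evaluation ----

ex_eval_num <- function(e, env = numeric(0), tval = 0) {
  ev <- function(x) {
    switch(x$t,
      num = rq_to_double(x$q),
      sym = {
        v <- env[[x$name]]
        if (is.null(v) || is.na(v)) stop("unbound symbol: ", x$name)
        as.numeric(v)
      },
      time = tval,
      call = {
        a <- lapply(x$args, ev)
        switch(x$op,
          "+" = Reduce(`+`, a, 0),
          "-" = a[[1]] - a[[2]],
          "neg" = -a[[1]],
          "*" = Reduce(`*`, a, 1),
          "/" = a[[1]] / a[[2]],
          "^" = a[[1]]^a[[2]],
          exp = exp(a[[1]]),
          ln = log(a[[1]]),
          log = log(a[[2]], base = a[[1]]),
          sin = sin(a[[1]]),
          cos = cos(a[[1]]),
          tan = tan(a[[1]]),
          abs = abs(a[[1]]),
          pi = pi,
          ee = exp(1),
          stop("cannot evaluate op numerically: ", x$op)
        )
      },
      funcall = stop("cannot evaluate uninlined function call: ", x$fn),
      stop("cannot evaluate node: ", x$t)
    )
  }
  ev(e)
}

# ---- exact constant evaluation with irrationality detection ----

#' Evaluate a constant expression exactly, flagging irrational results
#'
#' Expressions built from rational constants under `+`, `-`, `*`, `/` and
#' integer powers evaluate to exact rationals. A transcendental head applied
#' to anything but its trivial identity argument (`exp(0)`, `ln(1)`,
#' `sin(0)`, ...), the constants pi and e, and non-integer powers of
#' non-perfect-powers are flagged irrational. The detection is conservative
#' by construction: a value that merely might be irrational is flagged.
#'
#' @param expr an expression tree.
#' @param env a named list binding symbols to exact rationals (class `rq`).
#' @return `list(irrational = FALSE, value = <rq>)` or
#'   `list(irrational = TRUE, reason = <chr>)`.
#' @examples
#' eval_constant(ex_call("exp", list(ex_num(0))), list())  # rational 1
#' @export
eval_constant <- function(expr, env = list()) {
  irr <- function(reason) structure(list(irrational = TRUE, reason = reason), class = "const_eval")
  rat <- function(q) structure(list(irrational = FALSE, value = q), class = "const_eval")
  ev <- function(x) {
    switch(x$t,
      num = rat(x$q),
      sym = {
        v <- env[[x$name]]
        if (is.null(v)) stop("unbound symbol in constant expression: ", x$name)
        if (inherits(v, "const_eval")) return(v)
        rat(v)
      },
      time = stop("time symbol in constant expression"),
      call = {
        if (x$op == "pi") return(irr("pi"))
        if (x$op == "ee") return(irr("e"))
        a <- lapply(x$args, ev)
        bad <- which(vapply(a, function(z) z$irrational, logical(1)))
        if (length(bad)) return(irr(a[[bad[1]]]$reason))
        vals <- lapply(a, function(z) z$value)
        switch(x$op,
          "+" = rat(rq_sum(vals)),
          "-" = rat(rq_sub(vals[[1]], vals[[2]])),
          "neg" = rat(rq_neg(vals[[1]])),
          "*" = rat(Reduce(rq_mul, vals, rq_one())),
          "/" = {
            if (rq_is_zero(vals[[2]])) stop("division by zero in constant expression")
            rat(rq_div(vals[[1]], vals[[2]]))
          },
          "^" = {
            base <- vals[[1]]; expo <- vals[[2]]
            if (rq_is_int(expo)) {
              e_int <- bi_to_num(expo$n)
              if (rq_is_zero(base) && e_int < 0) stop("division by zero in constant expression")
              return(rat(rq_pow_int(base, e_int)))
            }
            if (rq_is_zero(base)) {
              if (rq_sign(expo) > 0) return(rat(rq_zero()))
              stop("division by zero in constant expression")
            }
            if (rq_is_one(base)) return(rat(rq_one()))
            den <- bi_to_num(expo$d)
            root <- rq_nth_root_exact(base, den)
            if (is.null(root)) return(irr(paste0("non-integer power ", rq_to_str(base), "^", rq_to_str(expo))))
            rat(rq_pow_int(root, bi_to_num(expo$n)))
          },
          exp = if (rq_is_zero(vals[[1]])) rat(rq_one()) else irr("exp of nonzero argument"),
          ln = if (rq_is_one(vals[[1]])) rat(rq_zero()) else irr("ln of non-unit argument"),
          log = {
            if (rq_is_one(vals[[2]])) rat(rq_zero())
            else if (rq_eq(vals[[1]], vals[[2]])) rat(rq_one())
            else irr("log of non-trivial argument")
          },
          sin = if (rq_is_zero(vals[[1]])) rat(rq_zero()) else irr("sin of nonzero argument"),
          tan = if (rq_is_zero(vals[[1]])) rat(rq_zero()) else irr("tan of nonzero argument"),
          cos = if (rq_is_zero(vals[[1]])) rat(rq_one()) else irr("cos of nonzero argument"),
          abs = rat(rq_abs(vals[[1]])),
          stop("unsupported head in constant expression: ", x$op)
        )
      },
      funcall = stop("uninlined function call in constant expression: ", x$fn),
      stop("cannot evaluate node: ", x$t)
    )
  }
  ev(expr)
}

# ---- sparse multivariate polynomial expansion over exact rationals ----
#
# A poly is a named list of terms keyed by a canonical monomial string;
# each term is list(c = rq, p = named numeric exponent vector).  The time
# symbol is the variable "t" (species/parameter names never collide with it
# after canonical renaming).  Returns NULL when the expression is not a
# polynomial in its symbols.

poly_key <- function(p) {
  p <- p[p != 0]
  if (!length(p)) return("1")
  nm <- sort(names(p))
  paste(paste0(nm, "^", p[nm]), collapse = "*")
}

poly_const <- function(q) {
  if (rq_is_zero(q)) return(structure(list(), class = "sbpoly"))
  structure(stats::setNames(list(list(c = q, p = numeric(0))), "1"), class = "sbpoly")
}

poly_var <- function(name) {
  p <- stats::setNames(1, name)
  structure(stats::setNames(list(list(c = rq_one(), p = p)), poly_key(p)), class = "sbpoly")
}

poly_add <- function(a, b) {
  out <- unclass(a)
  for (k in names(b)) {
    if (is.null(out[[k]])) {
      out[[k]] <- b[[k]]
    } else {
      s <- rq_add(out[[k]]$c, b[[k]]$c)
      if (rq_is_zero(s)) out[[k]] <- NULL else out[[k]]$c <- s
    }
  }
  structure(out, class = "sbpoly")
}

poly_neg <- function(a) {
  out <- lapply(unclass(a), function(tm) {
    tm$c <- rq_neg(tm$c)
    tm
  })
  structure(out, class = "sbpoly")
}

poly_scale <- function(a, q) {
  if (rq_is_zero(q)) return(poly_const(rq_zero()))
  out <- lapply(unclass(a), function(tm) {
    tm$c <- rq_mul(tm$c, q)
    tm
  })
  structure(out, class = "sbpoly")
}

mono_mul <- function(p1, p2) {
  all <- union(names(p1), names(p2))
  v <- stats::setNames(numeric(length(all)), all)
  v[names(p1)] <- v[names(p1)] + p1
  v[names(p2)] <- v[names(p2)] + p2
  v[v != 0]
}

poly_mul <- function(a, b) {
  out <- list()
  for (ta in unclass(a)) {
    for (tb in unclass(b)) {
      p <- mono_mul(ta$p, tb$p)
      k <- poly_key(p)
      cc <- rq_mul(ta$c, tb$c)
      if (is.null(out[[k]])) {
        out[[k]] <- list(c = cc, p = p)
      } else {
        s <- rq_add(out[[k]]$c, cc)
        if (rq_is_zero(s)) out[[k]] <- NULL else out[[k]]$c <- s
      }
    }
  }
  structure(out, class = "sbpoly")
}

poly_pow <- function(a, n) {
  r <- poly_const(rq_one())
  for (i in seq_len(n)) r <- poly_mul(r, a)
  r
}

poly_is_zero <- function(a) length(a) == 0

poly_is_const <- function(a) {
  length(a) == 0 || (length(a) == 1 && !is.null(a[["1"]]))
}

# expression -> poly, or NULL if not polynomial in all its symbols
ex_poly <- function(e) {
  pv <- function(x) {
    switch(x$t,
      num = poly_const(x$q),
      sym = poly_var(x$name),
      time = poly_var("t"),
      call = {
        switch(x$op,
          "+" = {
            args <- lapply(x$args, pv)
            if (any(vapply(args, is.null, logical(1)))) return(NULL)
            Reduce(poly_add, args, poly_const(rq_zero()))
          },
          "-" = {
            a <- pv(x$args[[1]]); b <- pv(x$args[[2]])
            if (is.null(a) || is.null(b)) return(NULL)
            poly_add(a, poly_neg(b))
          },
          "neg" = {
            a <- pv(x$args[[1]])
            if (is.null(a)) return(NULL)
            poly_neg(a)
          },
          "*" = {
            args <- lapply(x$args, pv)
            if (any(vapply(args, is.null, logical(1)))) return(NULL)
            Reduce(poly_mul, args, poly_const(rq_one()))
          },
          "/" = {
            a <- pv(x$args[[1]]); b <- pv(x$args[[2]])
            if (is.null(a) || is.null(b)) return(NULL)
            if (!poly_is_const(b)) return(NULL)
            if (poly_is_zero(b)) stop("division by zero polynomial")
            poly_scale(a, rq_inv(b[["1"]]$c))
          },
          "^" = {
            expo <- x$args[[2]]
            if (expo$t != "num" || !rq_is_int(expo$q)) return(NULL)
            n <- bi_to_num(expo$q$n)
            base <- pv(x$args[[1]])
            if (is.null(base)) return(NULL)
            if (n < 0) {
              if (!poly_is_const(base)) return(NULL)
              if (poly_is_zero(base)) stop("division by zero polynomial")
              return(poly_const(rq_pow_int(base[["1"]]$c, n)))
            }
            poly_pow(base, n)
          },
          NULL
        )
      },
      funcall = NULL,
      NULL
    )
  }
  pv(e)
}

# rational normal form: list(num = poly, den = poly), or NULL if the
# expression involves transcendental heads
ex_ratpoly <- function(e) {
  rp <- function(x) {
    switch(x$t,
      num = list(num = poly_const(x$q), den = poly_const(rq_one())),
      sym = list(num = poly_var(x$name), den = poly_const(rq_one())),
      time = list(num = poly_var("t"), den = poly_const(rq_one())),
      call = {
        switch(x$op,
          "+" = {
            args <- lapply(x$args, rp)
            if (any(vapply(args, is.null, logical(1)))) return(NULL)
            Reduce(function(a, b) {
              list(
                num = poly_add(poly_mul(a$num, b$den), poly_mul(b$num, a$den)),
                den = poly_mul(a$den, b$den)
              )
            }, args)
          },
          "-" = {
            a <- rp(x$args[[1]]); b <- rp(x$args[[2]])
            if (is.null(a) || is.null(b)) return(NULL)
            list(
              num = poly_add(poly_mul(a$num, b$den), poly_neg(poly_mul(b$num, a$den))),
              den = poly_mul(a$den, b$den)
            )
          },
          "neg" = {
            a <- rp(x$args[[1]])
            if (is.null(a)) return(NULL)
            list(num = poly_neg(a$num), den = a$den)
          },
          "*" = {
            args <- lapply(x$args, rp)
            if (any(vapply(args, is.null, logical(1)))) return(NULL)
            Reduce(function(a, b) list(num = poly_mul(a$num, b$num), den = poly_mul(a$den, b$den)), args)
          },
          "/" = {
            a <- rp(x$args[[1]]); b <- rp(x$args[[2]])
            if (is.null(a) || is.null(b)) return(NULL)
            if (poly_is_zero(b$num)) stop("division by zero")
            list(num = poly_mul(a$num, b$den), den = poly_mul(a$den, b$num))
          },
          "^" = {
            expo <- x$args[[2]]
            if (expo$t != "num" || !rq_is_int(expo$q)) return(NULL)
            n <- bi_to_num(expo$q$n)
            a <- rp(x$args[[1]])
            if (is.null(a)) return(NULL)
            if (n >= 0) {
              list(num = poly_pow(a$num, n), den = poly_pow(a$den, n))
            } else {
              if (poly_is_zero(a$num)) stop("division by zero")
              list(num = poly_pow(a$den, -n), den = poly_pow(a$num, -n))
            }
          },
          NULL
        )
      },
      funcall = NULL,
      NULL
    )
  }
  rp(e)
}

# symbolic equality: exact on the rational-function field when both sides
# admit a rational normal form; falls back to structural identity
ex_equal_sym <- function(a, b) {
  ra <- tryCatch(ex_ratpoly(a), error = function(e) NULL)
  rb <- tryCatch(ex_ratpoly(b), error = function(e) NULL)
  if (!is.null(ra) && !is.null(rb)) {
    diff <- poly_add(poly_mul(ra$num, rb$den), poly_neg(poly_mul(rb$num, ra$den)))
    return(poly_is_zero(diff))
  }
  ex_strip_lex <- function(x) {
    x$lex <- NULL
    if (x$t %in% c("call", "funcall")) x$args <- lapply(x$args, ex_strip_lex)
    x
  }
  identical(ex_strip_lex(a), ex_strip_lex(b))
}

# ---- classification (polynomial / rational / other) ----

.cls_rank <- c(polynomial = 1L, rational = 2L, other = 3L)
cls_max <- function(...) {
  v <- c(...)
  names(.cls_rank)[max(.cls_rank[v])]
}

# class of an expression as a function of the state variables (and time);
# parameters may enter through any rational operation
classify_expr <- function(e, statevars) {
  free_of_state <- function(x) !ex_uses_any(x, statevars, or_time = TRUE)
  cls <- function(x) {
    switch(x$t,
      num = "polynomial",
      sym = "polynomial",
      time = "polynomial",
      call = {
        switch(x$op,
          "+" = ,
          "-" = ,
          "neg" = ,
          "*" = do.call(cls_max, lapply(x$args, cls)),
          "/" = {
            a <- cls(x$args[[1]])
            b <- cls(x$args[[2]])
            if (a == "other" || b == "other") return("other")
            if (free_of_state(x$args[[2]])) a else cls_max(a, "rational")
          },
          "^" = {
            expo <- x$args[[2]]
            base_cls <- cls(x$args[[1]])
            if (expo$t == "num" && rq_is_int(expo$q)) {
              n <- bi_to_num(expo$q$n)
              if (base_cls == "other") return("other")
              if (n >= 0) return(base_cls)
              if (free_of_state(x$args[[1]])) return(base_cls)
              return(cls_max(base_cls, "rational"))
            }
            "other"
          },
          "pi" = ,
          "ee" = ,
          "exp" = ,
          "ln" = ,
          "log" = ,
          "sin" = ,
          "cos" = ,
          "tan" = ,
          "abs" = "other",
          "other"
        )
      },
      funcall = "other",
      "other"
    )
  }
  cls(e)
}

# ---- generalized-monomial decomposition for the mass-action test ----
#
# Decomposes e as (factor free of species and time) * prod(species^exponent)
# with numeric exponents; returns the named exponent vector, or NULL when no
# such decomposition is found (the conservative failure direction).

ex_monomial <- function(e, species) {
  emptyv <- stats::setNames(numeric(0), character(0))
  addv <- function(a, b) {
    all <- union(names(a), names(b))
    v <- stats::setNames(numeric(length(all)), all)
    v[names(a)] <- v[names(a)] + a
    v[names(b)] <- v[names(b)] + b
    v[v != 0]
  }
  dec <- function(x) {
    if (!ex_uses_any(x, species, or_time = TRUE)) return(emptyv)
    switch(x$t,
      sym = if (x$name %in% species) stats::setNames(1, x$name) else emptyv,
      time = NULL,
      call = {
        switch(x$op,
          "*" = {
            parts <- lapply(x$args, dec)
            if (any(vapply(parts, is.null, logical(1)))) return(NULL)
            Reduce(addv, parts, emptyv)
          },
          "neg" = dec(x$args[[1]]),
          "/" = {
            a <- dec(x$args[[1]])
            b <- dec(x$args[[2]])
            if (is.null(a) || is.null(b)) return(NULL)
            addv(a, -b)
          },
          "^" = {
            expo <- x$args[[2]]
            if (ex_uses_any(expo, species, or_time = TRUE)) return(NULL)
            if (expo$t != "num") return(NULL)
            ev <- rq_to_double(expo$q)
            base <- dec(x$args[[1]])
            if (is.null(base)) return(NULL)
            base * ev
          },
          NULL
        )
      },
      NULL
    )
  }
  dec(e)
}

# ---- rendering into computer-algebra dialects ----

# precedence levels: 1 sum, 2 product, 3 unary minus, 4 power, 5 atom
ex_render <- function(e, dialect = c("plain", "maple", "reduce", "sagemath", "latex")) {
  dialect <- match.arg(dialect)
  ltx <- dialect == "latex"
  paren <- function(s, prec, need) if (prec < need) paste0(if (ltx) "\\left(" else "(", s, if (ltx) "\\right)" else ")") else s
  fn_name <- function(op) {
    if (!ltx) {
      switch(op,
        ln = switch(dialect, maple = "ln", reduce = "log", sagemath = "log", plain = "ln"),
        op
      )
    } else {
      switch(op, exp = "\\exp", ln = "\\ln", sin = "\\sin", cos = "\\cos", tan = "\\tan", abs = "\\operatorname{abs}", op)
    }
  }
  rend <- function(x) {
    switch(x$t,
      num = {
        q <- x$q
        if (rq_is_int(q)) {
          s <- bi_to_str(q$n)
          list(s = s, p = if (rq_sign(q) < 0) 3 else 5)
        } else if (ltx) {
          neg <- rq_sign(q) < 0
          s <- paste0(
            if (neg) "-" else "",
            "\\frac{", bi_to_str(bi_abs(q$n)), "}{", bi_to_str(q$d), "}"
          )
          list(s = s, p = if (neg) 3 else 5)
        } else {
          list(s = paste0(bi_to_str(q$n), "/", bi_to_str(q$d)), p = 2)
        }
      },
      sym = {
        if (ltx) {
          m <- regmatches(x$name, regexec("^([A-Za-z]+)([0-9]+)$", x$name))[[1]]
          s <- if (length(m) == 3) paste0(m[2], "_{", m[3], "}") else paste0("\\mathit{", x$name, "}")
          list(s = s, p = 5)
        } else {
          list(s = x$name, p = 5)
        }
      },
      time = list(s = "t", p = 5),
      call = {
        op <- x$op
        if (op == "+") {
          parts <- lapply(x$args, rend)
          s <- ""
          for (i in seq_along(parts)) {
            pi_ <- parts[[i]]
            if (i == 1) {
              s <- paren(pi_$s, pi_$p, 1)
            } else if (grepl("^-", pi_$s)) {
              s <- paste0(s, " - ", paren(substring(pi_$s, 2), pi_$p, 2))
            } else {
              s <- paste0(s, " + ", paren(pi_$s, pi_$p, 2))
            }
          }
          return(list(s = s, p = 1))
        }
        if (op == "-") {
          a <- rend(x$args[[1]]); b <- rend(x$args[[2]])
          return(list(s = paste0(paren(a$s, a$p, 1), " - ", paren(b$s, b$p, 2)), p = 1))
        }
        if (op == "neg") {
          a <- rend(x$args[[1]])
          return(list(s = paste0("-", paren(a$s, a$p, 2)), p = 3))
        }
        if (op == "*") {
          parts <- vapply(x$args, function(ar) {
            rr <- rend(ar)
            paren(rr$s, rr$p, 2)
          }, character(1))
          return(list(s = paste(parts, collapse = if (ltx) " \\cdot " else "*"), p = 2))
        }
        if (op == "/") {
          a <- rend(x$args[[1]]); b <- rend(x$args[[2]])
          if (ltx) {
            return(list(s = paste0("\\frac{", a$s, "}{", b$s, "}"), p = 5))
          }
          return(list(s = paste0(paren(a$s, a$p, 2), "/", paren(b$s, b$p, 3)), p = 2))
        }
        if (op == "^") {
          a <- rend(x$args[[1]]); b <- rend(x$args[[2]])
          if (ltx) {
            return(list(s = paste0("{", paren(a$s, a$p, 4), "}^{", b$s, "}"), p = 4))
          }
          return(list(s = paste0(paren(a$s, a$p, 5), "^", paren(b$s, b$p, 5)), p = 4))
        }
        if (op == "pi") {
          return(list(s = switch(dialect, maple = "Pi", latex = "\\pi", "pi"), p = 5))
        }
        if (op == "ee") {
          return(list(s = switch(dialect, latex = "e", "exp(1)"), p = 5))
        }
        if (op == "log") {
          base <- rend(x$args[[1]]); arg <- rend(x$args[[2]])
          s <- switch(dialect,
            maple = paste0("log[", base$s, "](", arg$s, ")"),
            sagemath = paste0("log(", arg$s, ", ", base$s, ")"),
            latex = paste0("\\log_{", base$s, "}\\left(", arg$s, "\\right)"),
            paste0("log(", arg$s, ")/log(", base$s, ")")
          )
          return(list(s = s, p = if (dialect == "reduce" || dialect == "plain") 2 else 5))
        }
        if (startsWith(op, "unknown:")) stop("cannot render unsupported construct: ", op)
        args <- vapply(x$args, function(ar) rend(ar)$s, character(1))
        s <- if (ltx) {
          paste0(fn_name(op), "\\left(", paste(args, collapse = ", "), "\\right)")
        } else {
          paste0(fn_name(op), "(", paste(args, collapse = ", "), ")")
        }
        list(s = s, p = 5)
      },
      funcall = stop("cannot render uninlined function call: ", x$fn),
      stop("cannot render node: ", x$t)
    )
  }
  rend(e)$s
}

# ---- minimal expression parser for the SageMath dialect round-trip ----

sage_tokenize <- function(s) {
  tokens <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9]$", substr(s, j, j))) j <- j + 1L
      if (j <= n && substr(s, j, j) == ".") stop("floating literal in exact export: ", substr(s, i, j))
      tokens[[length(tokens) + 1L]] <- list(type = "int", val = substr(s, i, j - 1L))
      i <- j
    } else if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(s, j, j))) j <- j + 1L
      tokens[[length(tokens) + 1L]] <- list(type = "name", val = substr(s, i, j - 1L))
      i <- j
    } else if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch)
      i <- i + 1L
    } else {
      stop("unexpected character in expression: ", ch)
    }
  }
  tokens
}

sage_parse_expr <- function(text) {
  toks <- sage_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function(type = NULL) {
    tk <- peek()
    if (is.null(tk)) stop("unexpected end of expression")
    if (!is.null(type) && tk$type != type) stop("expected '", type, "' in expression")
    pos <<- pos + 1L
    tk
  }
  parse_sum <- function() {
    lhs <- if (!is.null(peek()) && peek()$type == "-") {
      take()
      e_neg(parse_term())
    } else {
      parse_term()
    }
    repeat {
      tk <- peek()
      if (is.null(tk) || !(tk$type %in% c("+", "-"))) return(lhs)
      take()
      rhs <- parse_term()
      lhs <- if (tk$type == "+") ex_call("+", list(lhs, rhs)) else e_sub(lhs, rhs)
    }
  }
  parse_term <- function() {
    lhs <- parse_power()
    repeat {
      tk <- peek()
      if (is.null(tk) || !(tk$type %in% c("*", "/"))) return(lhs)
      take()
      rhs <- parse_power()
      lhs <- if (tk$type == "*") ex_call("*", list(lhs, rhs)) else e_div(lhs, rhs)
    }
  }
  parse_power <- function() {
    base <- parse_atom()
    tk <- peek()
    if (!is.null(tk) && tk$type == "^") {
      take()
      expo <- if (!is.null(peek()) && peek()$type == "-") {
        take()
        e_neg(parse_atom())
      } else {
        parse_atom()
      }
      return(e_pow(base, expo))
    }
    base
  }
  parse_atom <- function() {
    tk <- take()
    if (tk$type == "int") return(ex_num(rq_bi(bi_from_str(tk$val))))
    if (tk$type == "(") {
      e <- parse_sum()
      take(")")
      return(e)
    }
    if (tk$type == "name") {
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "(") {
        take("(")
        args <- list()
        if (!is.null(peek()) && peek()$type != ")") {
          args[[1]] <- parse_sum()
          while (!is.null(peek()) && peek()$type == ",") {
            take(",")
            args[[length(args) + 1L]] <- parse_sum()
          }
        }
        take(")")
        op <- tk$val
        if (op == "log" && length(args) == 2) return(ex_call("log", list(args[[2]], args[[1]])))
        if (op == "log") return(ex_call("ln", args))
        return(ex_call(op, args))
      }
      if (tk$val == "t") return(ex_time())
      if (tk$val == "pi") return(ex_call("pi", list()))
      return(ex_sym(tk$val))
    }
    stop("unexpected token in expression")
  }
  out <- parse_sum()
  if (pos <= length(toks)) stop("trailing tokens in expression")
  out
}
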