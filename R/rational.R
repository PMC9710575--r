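# Exact rational numbers over the bigint kernel, plus the exact linear
# algebra the converter needs (fraction-free rank, reduced row echelon form,
# rational nullspaces).  A rational is a list(n = bigint, d = bigint > 0)
# with gcd(|n|, d) = 1, class "rq".

rq_raw <- function(n, d) structure(list(n = n, d = d), class = "rq")

rq_norm <- function(n, d) {
  stopifnot(!bi_is_zero(d))
  if (d$s < 0L) {
    n <- bi_neg(n)
    d <- bi_neg(d)
  }
  if (bi_is_zero(n)) return(rq_raw(bi_zero(), bi_one()))
  g <- bi_gcd(n, d)
  if (!bi_is_one(g)) {
    n <- bi_div_exact(n, g)
    d <- bi_div_exact(d, g)
  }
  rq_raw(n, d)
}

is_rq <- function(x) inherits(x, "rq")

rq_zero <- function() rq_raw(bi_zero(), bi_one())
rq_one <- function() rq_raw(bi_one(), bi_one())

# from an integer-valued double
rq_int <- function(x) rq_raw(bi_from_num(x), bi_one())

rq_bi <- function(n, d = bi_one()) rq_norm(n, d)

rq_is_zero <- function(q) bi_is_zero(q$n)
rq_is_one <- function(q) bi_is_one(q$n) && bi_is_one(q$d)
rq_is_int <- function(q) bi_is_one(q$d)

rq_add <- function(a, b) rq_norm(bi_add(bi_mul(a$n, b$d), bi_mul(b$n, a$d)), bi_mul(a$d, b$d))
rq_sub <- function(a, b) rq_norm(bi_sub(bi_mul(a$n, b$d), bi_mul(b$n, a$d)), bi_mul(a$d, b$d))
rq_mul <- function(a, b) rq_norm(bi_mul(a$n, b$n), bi_mul(a$d, b$d))
rq_neg <- function(a) rq_raw(bi_neg(a$n), a$d)
rq_abs <- function(a) rq_raw(bi_abs(a$n), a$d)

rq_div <- function(a, b) {
  if (rq_is_zero(b)) stop("rational division by zero")
  rq_norm(bi_mul(a$n, b$d), bi_mul(a$d, b$n))
}

rq_inv <- function(a) {
  if (rq_is_zero(a)) stop("rational division by zero")
  rq_norm(a$d, a$n)
}

rq_cmp <- function(a, b) bi_cmp(bi_mul(a$n, b$d), bi_mul(b$n, a$d))
rq_eq <- function(a, b) bi_eq(a$n, b$n) && bi_eq(a$d, b$d)
rq_sign <- function(a) a$n$s

# q^e for an R integer e (possibly negative)
rq_pow_int <- function(q, e) {
  stopifnot(e == floor(e))
  if (e == 0) return(rq_one())
  if (e < 0) {
    q <- rq_inv(q)
    e <- -e
  }
  rq_raw(bi_pow(q$n, e), bi_pow(q$d, e))
}

# exact b-th root when q is a perfect b-th power of a rational, else NULL
rq_nth_root_exact <- function(q, b) {
  stopifnot(b >= 1)
  if (rq_sign(q) < 0) {
    if (b %% 2 == 0) return(NULL)
    r <- rq_nth_root_exact(rq_neg(q), b)
    return(if (is.null(r)) NULL else rq_neg(r))
  }
  rn <- bi_nth_root_exact(q$n, b)
  if (is.null(rn)) return(NULL)
  rd <- bi_nth_root_exact(q$d, b)
  if (is.null(rd)) return(NULL)
  rq_norm(rn, rd)
}

rq_to_double <- function(q) bi_to_num(q$n) / bi_to_num(q$d)

rq_to_str <- function(q) {
  if (bi_is_one(q$d)) bi_to_str(q$n) else paste0(bi_to_str(q$n), "/", bi_to_str(q$d))
}

#' @export
format.rq <- function(x, ...) rq_to_str(x)

#' @export
print.rq <- function(x, ...) {
  cat(rq_to_str(x), "\n")
  invisible(x)
}

#' Convert a decimal numeral (lexical string) to an exact rational
#'
#' Interprets the decimal or scientific-notation text of a numeric literal
#' exactly: `"0.1"` becomes 1/10, not the nearest binary double. This is how
#' all SBML attribute values and `<cn>` elements enter the converter, so no
#' floating-point representation error is ever introduced.
#'
#' @param lexical a character scalar such as `"0.5"`, `"-3"`, `"1e-3"`,
#'   `"3.14159"`.
#' @return an exact rational (class `rq`); format it with `format()` to get
#'   the `"p/q"` form.
#' @examples
#' format(literal_to_rational("0.5"))    # "1/2"
#' format(literal_to_rational("1e-3"))   # "1/1000"
#' @export
literal_to_rational <- function(lexical) {
  s <- trimws(as.character(lexical))
  if (!length(s) || is.na(s) || s == "") stop("invalid numeric literal: empty")
  if (grepl("nan|inf", s, ignore.case = TRUE)) {
    stop("invalid numeric literal: ", s)
  }
  if (!grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)) {
    stop("invalid numeric literal: ", s)
  }
  sgn <- 1L
  if (grepl("^[+-]", s)) {
    if (substr(s, 1, 1) == "-") sgn <- -1L
    s <- substring(s, 2)
  }
  exp10 <- 0
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]")[[1]]
    s <- parts[1]
    exp10 <- as.numeric(parts[2])
  }
  intpart <- s
  fracpart <- ""
  if (grepl("\\.", s)) {
    parts <- strsplit(s, "\\.", fixed = FALSE)[[1]]
    intpart <- if (length(parts) >= 1) parts[1] else ""
    fracpart <- if (length(parts) >= 2) parts[2] else ""
  }
  digits <- paste0(intpart, fracpart)
  if (digits == "") stop("invalid numeric literal")
  n <- bi_from_str(digits)
  if (sgn < 0) n <- bi_neg(n)
  shift <- exp10 - nchar(fracpart)
  if (shift >= 0) {
    rq_norm(bi_mul(n, bi_pow(bi_from_num(10), shift)), bi_one())
  } else {
    rq_norm(n, bi_pow(bi_from_num(10), -shift))
  }
}

#' Convert an IEEE-754 double to the exact rational it represents
#'
#' Every finite double is a dyadic rational; this returns that rational
#' exactly. It is the fallback conversion for values only reachable as
#' binaries (the lexical route, [literal_to_rational()], is preferred when
#' the original decimal text is available).
#'
#' @param v a finite double.
#' @return an exact rational (class `rq`).
#' @examples
#' format(double_to_rational(0.25))  # "1/4"
#' format(double_to_rational(-2))    # "-2"
#' @export
double_to_rational <- function(v) {
  if (!is.finite(v)) stop("invalid value: NaN or infinite")
  if (v == 0) return(rq_zero())
  sgn <- if (v < 0) -1L else 1L
  av <- abs(v)
  if (av == floor(av) && av < 2^53) {
    n <- bi_from_num(av)
    if (sgn < 0) n <- bi_neg(n)
    return(rq_raw(n, bi_one()))
  }
  e <- floor(log2(av))
  mant <- av / 2^(e - 52)
  while (mant >= 2^53) {
    e <- e + 1
    mant <- av / 2^(e - 52)
  }
  while (mant < 2^52 && e > -1074 + 52) {
    e <- e - 1
    mant <- av / 2^(e - 52)
  }
  # strip trailing zero bits so the fast integer path stays small
  while (mant %% 2 == 0 && mant > 0) {
    mant <- mant / 2
    e <- e + 1
  }
  k <- e - 52
  n <- bi_from_num(mant)
  if (sgn < 0) n <- bi_neg(n)
  if (k >= 0) {
    rq_raw(bi_mul(n, bi_pow(bi_from_num(2), k)), bi_one())
  } else {
    rq_raw(n, bi_pow(bi_from_num(2), -k))
  }
}

# small helpers over lists of rationals
rq_sum <- function(lst) Reduce(rq_add, lst, rq_zero())
rq_dot <- function(a, b) rq_sum(Map(rq_mul, a, b))

# ---- exact matrices: R list-matrices of rq entries ----

rmat_new <- function(n, r) matrix(rep(list(rq_zero()), n * r), nrow = n, ncol = r)

rmat_dim <- function(M) dim(M)

rmat_from_num <- function(A) {
  M <- rmat_new(nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) M[[i, j]] <- rq_int(A[i, j])
  M
}

rmat_to_num <- function(M) {
  A <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) A[i, j] <- rq_to_double(M[[i, j]])
  A
}

rmat_to_char <- function(M) {
  A <- matrix("", nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) A[i, j] <- rq_to_str(M[[i, j]])
  A
}

rmat_transpose <- function(M) {
  T <- rmat_new(ncol(M), nrow(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) T[[j, i]] <- M[[i, j]]
  T
}

# clear denominators of one row, returning a list of bigints
row_to_bigints <- function(M, i) {
  den <- bi_one()
  for (j in seq_len(ncol(M))) {
    dj <- M[[i, j]]$d
    g <- bi_gcd(den, dj)
    den <- bi_mul(den, bi_div_exact(dj, g)) # lcm
  }
  lapply(seq_len(ncol(M)), function(j) {
    q <- M[[i, j]]
    bi_mul(q$n, bi_div_exact(den, q$d))
  })
}

# exact rank via fraction-free (Bareiss) elimination after clearing row
# denominators (row scaling does not change rank)
rmat_rank <- function(M) {
  n <- nrow(M); r <- ncol(M)
  if (n == 0 || r == 0) return(0L)
  B <- vector("list", n)
  for (i in seq_len(n)) B[[i]] <- row_to_bigints(M, i)
  rank <- 0L
  prev <- bi_one()
  cc <- 1L
  while (cc <= r && rank < n) {
    piv <- 0L
    for (i in (rank + 1L):n) {
      if (!bi_is_zero(B[[i]][[cc]])) {
        piv <- i
        break
      }
    }
    if (piv == 0L) {
      cc <- cc + 1L
      next
    }
    if (piv != rank + 1L) {
      tmp <- B[[piv]]
      B[[piv]] <- B[[rank + 1L]]
      B[[rank + 1L]] <- tmp
    }
    p <- B[[rank + 1L]][[cc]]
    if (rank + 2L <= n) {
      for (i in (rank + 2L):n) {
        bic <- B[[i]][[cc]]
        for (j in seq_len(r)) {
          if (j == cc) next
          B[[i]][[j]] <- bi_div_exact(
            bi_sub(bi_mul(p, B[[i]][[j]]), bi_mul(bic, B[[rank + 1L]][[j]])),
            prev
          )
        }
        B[[i]][[cc]] <- bi_zero()
      }
    }
    prev <- p
    rank <- rank + 1L
    cc <- cc + 1L
  }
  rank
}

# reduced row echelon form with exact rational arithmetic
rmat_rref <- function(M) {
  n <- nrow(M); r <- ncol(M)
  M <- M # copy-on-write
  pivots <- integer(0)
  row <- 1L
  for (cc in seq_len(r)) {
    if (row > n) break
    piv <- 0L
    for (i in row:n) {
      if (!rq_is_zero(M[[i, cc]])) {
        piv <- i
        break
      }
    }
    if (piv == 0L) next
    if (piv != row) {
      for (j in seq_len(r)) {
        tmp <- M[[piv, j]]
        M[[piv, j]] <- M[[row, j]]
        M[[row, j]] <- tmp
      }
    }
    pv <- M[[row, cc]]
    for (j in seq_len(r)) M[[row, j]] <- rq_div(M[[row, j]], pv)
    for (i in seq_len(n)) {
      if (i == row) next
      f <- M[[i, cc]]
      if (rq_is_zero(f)) next
      for (j in seq_len(r)) {
        M[[i, j]] <- rq_sub(M[[i, j]], rq_mul(f, M[[row, j]]))
      }
    }
    pivots <- c(pivots, cc)
    row <- row + 1L
  }
  list(R = M, pivots = pivots)
}

# basis of { y : M %*% y = 0 }, as a list of rq vectors (length ncol(M))
rmat_nullspace <- function(M) {
  r <- ncol(M)
  if (r == 0) return(list())
  if (nrow(M) == 0) {
    return(lapply(seq_len(r), function(j) {
      v <- rep(list(rq_zero()), r)
      v[[j]] <- rq_one()
      v
    }))
  }
  rr <- rmat_rref(M)
  pivots <- rr$pivots
  free <- setdiff(seq_len(r), pivots)
  lapply(free, function(f) {
    v <- rep(list(rq_zero()), r)
    v[[f]] <- rq_one()
    for (i in seq_along(pivots)) {
      v[[pivots[i]]] <- rq_neg(rr$R[[i, f]])
    }
    v
  })
}

# scale an rq vector to a primitive integer vector with positive leading
# nonzero entry; returns a plain numeric vector (entries are small)
rq_vec_primitive <- function(v) {
  den <- bi_one()
  for (q in v) {
    g <- bi_gcd(den, q$d)
    den <- bi_mul(den, bi_div_exact(q$d, g))
  }
  ints <- lapply(v, function(q) bi_mul(q$n, bi_div_exact(den, q$d)))
  g <- bi_zero()
  for (b in ints) g <- bi_gcd(g, b)
  if (!bi_is_zero(g)) ints <- lapply(ints, function(b) bi_div_exact(b, g))
  x <- vapply(ints, bi_to_num, numeric(1))
  lead <- x[x != 0]
  if (length(lead) && lead[1] < 0) x <- -x
  x
}
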