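# Arbitrary-precision signed integers.
#
# Magnitudes are little-endian numeric vectors of base-2^24 limbs, so every
# limb product stays below 2^48 < 2^53 and plain doubles are exact carriers.
# Reaction-network matrices are tiny (entries rarely exceed a few digits), so
# schoolbook algorithms are deliberate; correctness and exactness are the
# point, not asymptotics.

.BI_BASE <- 16777216 # 2^24

bi_new <- function(s, m) list(s = as.integer(s), m = m)

bi_zero <- function() bi_new(0L, numeric(0))
bi_one <- function() bi_new(1L, 1)

bi_is_zero <- function(a) a$s == 0L

mag_norm <- function(m) {
  n <- length(m)
  while (n > 0 && m[n] == 0) n <- n - 1L
  if (n == length(m)) m else m[seq_len(n)]
}

# x must be a nonnegative integer-valued double < 2^53
mag_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  m <- numeric(0)
  while (x >= 1) {
    r <- x %% .BI_BASE
    m <- c(m, r)
    x <- (x - r) / .BI_BASE
  }
  m
}

mag_to_num <- function(m) {
  if (!length(m)) return(0)
  sum(m * .BI_BASE^(seq_along(m) - 1))
}

mag_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(sign(la - lb))
  if (la == 0L) return(0)
  for (i in la:1) if (a[i] != b[i]) return(sign(a[i] - b[i]))
  0
}

mag_add <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) < n) a <- c(a, numeric(n - length(a)))
  if (length(b) < n) b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    v <- s[i] + carry
    if (v >= .BI_BASE) {
      s[i] <- v - .BI_BASE
      carry <- 1
    } else {
      s[i] <- v
      carry <- 0
    }
  }
  if (carry) s <- c(s, 1)
  s
}

# assumes a >= b
mag_sub <- function(a, b) {
  n <- length(a)
  if (length(b) < n) b <- c(b, numeric(n - length(b)))
  d <- a - b
  borrow <- 0
  for (i in seq_len(n)) {
    v <- d[i] - borrow
    if (v < 0) {
      d[i] <- v + .BI_BASE
      borrow <- 1
    } else {
      d[i] <- v
      borrow <- 0
    }
  }
  stopifnot(borrow == 0)
  mag_norm(d)
}

mag_mul <- function(a, b) {
  if (!length(a) || !length(b)) return(numeric(0))
  la <- length(a); lb <- length(b)
  res <- numeric(la + lb)
  for (i in seq_len(la)) {
    ai <- a[i]
    if (ai == 0) next
    idx <- i:(i + lb - 1)
    res[idx] <- res[idx] + ai * b
    carry <- 0
    for (j in i:length(res)) {
      v <- res[j] + carry
      carry <- floor(v / .BI_BASE)
      res[j] <- v - carry * .BI_BASE
      if (carry == 0 && j >= i + lb) break
    }
    stopifnot(carry == 0)
  }
  mag_norm(res)
}

# multiply by a small scalar 0 <= d < 2^24
mag_mul_small <- function(a, d) {
  if (!length(a) || d == 0) return(numeric(0))
  v <- a * d
  carry <- 0
  for (i in seq_along(v)) {
    w <- v[i] + carry
    carry <- floor(w / .BI_BASE)
    v[i] <- w - carry * .BI_BASE
  }
  while (carry > 0) {
    w <- carry %% .BI_BASE
    v <- c(v, w)
    carry <- (carry - w) / .BI_BASE
  }
  mag_norm(v)
}

mag_add_small <- function(a, d) mag_add(a, mag_from_num(d))

# divide by a small scalar 1 <= d < 2^24; returns quotient and remainder
mag_divmod_small <- function(a, d) {
  stopifnot(d >= 1, d < .BI_BASE)
  if (!length(a)) return(list(q = numeric(0), r = 0))
  q <- numeric(length(a))
  r <- 0
  for (i in rev(seq_along(a))) {
    cur <- r * .BI_BASE + a[i]
    q[i] <- floor(cur / d)
    r <- cur - q[i] * d
  }
  list(q = mag_norm(q), r = r)
}

mag_shl1 <- function(m) {
  if (!length(m)) return(m)
  mag_mul_small(m, 2)
}

mag_bitlen <- function(m) {
  if (!length(m)) return(0L)
  top <- m[length(m)]
  b <- 0L
  while (top >= 1) {
    top <- floor(top / 2)
    b <- b + 1L
  }
  24L * (length(m) - 1L) + b
}

mag_getbit <- function(m, i) {
  idx <- i %/% 24L + 1L
  if (idx > length(m)) return(0)
  floor(m[idx] / 2^(i %% 24L)) %% 2
}

# general division with remainder on magnitudes: a = q*b + r, 0 <= r < b.
# Binary shift-and-subtract; operand sizes here are tiny.
mag_divmod <- function(a, b) {
  stopifnot(length(b) > 0)
  if (mag_cmp(a, b) < 0) return(list(q = numeric(0), r = a))
  if (length(b) == 1) {
    s <- mag_divmod_small(a, b[1])
    return(list(q = s$q, r = if (s$r == 0) numeric(0) else s$r))
  }
  nbits <- mag_bitlen(a)
  q <- numeric((nbits - 1) %/% 24 + 1)
  r <- numeric(0)
  for (i in (nbits - 1L):0L) {
    r <- mag_shl1(r)
    if (mag_getbit(a, i)) r <- mag_add(r, 1)
    if (mag_cmp(r, b) >= 0) {
      r <- mag_sub(r, b)
      q[i %/% 24L + 1L] <- q[i %/% 24L + 1L] + 2^(i %% 24L)
    }
  }
  list(q = mag_norm(q), r = r)
}

mag_gcd <- function(a, b) {
  # fast path: both fit exactly in doubles (<= 2 limbs < 2^48)
  if (length(a) <= 2 && length(b) <= 2) {
    x <- mag_to_num(a); y <- mag_to_num(b)
    while (y > 0) {
      t <- x %% y
      x <- y
      y <- t
    }
    return(mag_from_num(x))
  }
  while (length(b)) {
    r <- mag_divmod(a, b)$r
    a <- b
    b <- r
  }
  a
}

# ---- signed wrappers ----

bi_norm <- function(s, m) {
  m <- mag_norm(m)
  if (!length(m)) bi_new(0L, numeric(0)) else bi_new(s, m)
}

bi_from_num <- function(x) {
  stopifnot(is.finite(x), x == floor(x), abs(x) < 2^53)
  bi_norm(if (x < 0) -1L else 1L, mag_from_num(abs(x)))
}

bi_to_num <- function(a) a$s * mag_to_num(a$m)

bi_neg <- function(a) if (a$s == 0L) a else bi_new(-a$s, a$m)

bi_abs <- function(a) if (a$s < 0L) bi_new(1L, a$m) else a

bi_add <- function(a, b) {
  if (a$s == 0L) return(b)
  if (b$s == 0L) return(a)
  if (a$s == b$s) return(bi_new(a$s, mag_add(a$m, b$m)))
  cc <- mag_cmp(a$m, b$m)
  if (cc == 0) return(bi_zero())
  if (cc > 0) bi_new(a$s, mag_sub(a$m, b$m)) else bi_new(b$s, mag_sub(b$m, a$m))
}

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (a$s == 0L || b$s == 0L) return(bi_zero())
  bi_new(a$s * b$s, mag_mul(a$m, b$m))
}

bi_cmp <- function(a, b) {
  d <- bi_sub(a, b)
  d$s
}

bi_eq <- function(a, b) a$s == b$s && mag_cmp(a$m, b$m) == 0

bi_gcd <- function(a, b) {
  if (a$s == 0L) return(bi_abs(b))
  if (b$s == 0L) return(bi_abs(a))
  bi_new(1L, mag_gcd(a$m, b$m))
}

# exact division: b must divide a
bi_div_exact <- function(a, b) {
  stopifnot(b$s != 0L)
  if (a$s == 0L) return(bi_zero())
  dm <- mag_divmod(a$m, b$m)
  stopifnot(length(dm$r) == 0)
  bi_norm(a$s * b$s, dm$q)
}

bi_pow <- function(a, n) {
  stopifnot(n >= 0, n == floor(n))
  r <- bi_one()
  base <- a
  while (n > 0) {
    if (n %% 2 == 1) r <- bi_mul(r, base)
    base <- bi_mul(base, base)
    n <- n %/% 2
  }
  r
}

bi_is_one <- function(a) a$s == 1L && length(a$m) == 1 && a$m[1] == 1

# decimal string <-> bigint

bi_from_str <- function(s) {
  s <- trimws(s)
  sgn <- 1L
  if (grepl("^[+-]", s)) {
    if (substr(s, 1, 1) == "-") sgn <- -1L
    s <- substring(s, 2)
  }
  if (!grepl("^[0-9]+$", s)) stop("invalid integer literal: ", s)
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  m <- numeric(0)
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    take <- min(7L, n - pos + 1L)
    chunk <- as.numeric(substr(s, pos, pos + take - 1L))
    m <- mag_add(mag_mul(m, mag_from_num(10^take)), mag_from_num(chunk))
    pos <- pos + take
  }
  bi_norm(sgn, m)
}

bi_to_str <- function(a) {
  if (a$s == 0L) return("0")
  m <- a$m
  if (length(m) <= 2) {
    # fits exactly in a double
    return(paste0(if (a$s < 0L) "-" else "", sprintf("%.0f", mag_to_num(m))))
  }
  parts <- character(0)
  while (length(m)) {
    dm <- mag_divmod_small(m, 1e7)
    parts <- c(parts, if (length(dm$q)) sprintf("%07.0f", dm$r) else sprintf("%.0f", dm$r))
    m <- dm$q
  }
  paste0(if (a$s < 0L) "-" else "", paste(rev(parts), collapse = ""))
}

# integer n-th root if exact, else NULL
bi_nth_root_exact <- function(a, n) {
  stopifnot(a$s >= 0L, n >= 1)
  if (a$s == 0L) return(bi_zero())
  if (n == 1) return(a)
  guess <- round(bi_to_num(a)^(1 / n))
  for (cand in unique(pmax(0, guess + (-2:2)))) {
    cb <- bi_pow(bi_from_num(cand), n)
    if (bi_eq(cb, a)) return(bi_from_num(cand))
  }
  NULL
}
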