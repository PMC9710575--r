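# Linear conservation laws: a primitive-integer basis of the left kernel of
# the stoichiometric matrix restricted to dynamic species, with exact
# conserved totals when the initial values are known.

#' Integer basis of the left kernel of a stoichiometric matrix
#'
#' Returns linearly independent primitive integer vectors `y` with
#' `y %*% S_dyn == 0` exactly; their count is `nrow(S_dyn) - rank(S_dyn)`.
#' Each vector is normalized to coprime integer entries with a positive
#' leading nonzero coefficient. When simple pairwise combinations of basis
#' vectors yield all-nonnegative representatives, those are preferred
#' (best-effort; a full nonnegative-basis computation is out of scope).
#'
#' @param S_dyn an exact rational list-matrix: the stoichiometric matrix
#'   restricted to dynamic (non-boundary, non-assignment) species rows.
#' @return a list of integer vectors (plain numeric), possibly empty.
#' @export
left_kernel_basis <- function(S_dyn) {
  n <- nrow(S_dyn)
  if (n == 0) return(list())
  ns <- rmat_nullspace(rmat_transpose(S_dyn))
  basis <- lapply(ns, rq_vec_primitive)
  if (!length(basis)) return(basis)

  # best-effort nonnegativity: replace a mixed-sign vector by a nonnegative
  # pairwise integer combination when one exists and independence survives
  indep <- function(vecs) {
    M <- do.call(rbind, vecs)
    qr(M)$rank == length(vecs)
  }
  primitive <- function(v) {
    g <- 0
    for (a in abs(v)) {
      b <- a
      while (b > 0) {
        t <- g %% b
        g <- b
        b <- t
      }
    }
    if (g > 1) v <- v / g
    lead <- v[v != 0]
    if (length(lead) && lead[1] < 0) v <- -v
    v
  }
  for (i in seq_along(basis)) {
    v <- basis[[i]]
    if (all(v >= 0)) next
    for (j in seq_along(basis)) {
      if (i == j) next
      w <- basis[[j]]
      fixed <- FALSE
      for (cand in list(v + w, v + 2 * w, w - v, 2 * w - v)) {
        if (any(cand != 0) && all(cand >= 0)) {
          trial <- basis
          trial[[i]] <- primitive(cand)
          if (indep(trial)) {
            basis <- trial
            fixed <- TRUE
            break
          }
        }
      }
      if (fixed) break
    }
  }
  basis <- lapply(basis, primitive)
  basis
}

#' Conservation constraints from a left-kernel basis
#'
#' Each basis vector `y` becomes the formal constraint
#' `sum_i y[i] * x_i = total`, where the total is the exact rational
#' `sum_i y[i] * x_i(0)` when all involved initial values are known and a
#' fresh symbolic constant otherwise.
#'
#' @param basis a list of integer vectors from [left_kernel_basis()].
#' @param initial_values named list of exact rationals by `x`-name (entries
#'   may be missing).
#' @param dyn_vars character vector of the `x`-names of the dynamic species
#'   the basis vectors are indexed over.
#' @return a list of constraints
#'   `list(kind = "conservation", lhs, rhs, coefficients, total)`.
#' @export
conservation_constraints <- function(basis, initial_values, dyn_vars) {
  out <- list()
  sym_counter <- 0L
  for (b in seq_along(basis)) {
    y <- basis[[b]]
    terms <- list()
    total <- rq_zero()
    total_known <- TRUE
    for (i in seq_along(y)) {
      if (y[i] == 0) next
      xi <- dyn_vars[i]
      term <- if (y[i] == 1) {
        ex_sym(xi)
      } else if (y[i] == -1) {
        e_neg(ex_sym(xi))
      } else {
        e_mul(ex_num(rq_int(y[i])), ex_sym(xi))
      }
      terms[[length(terms) + 1L]] <- term
      x0 <- initial_values[[xi]]
      if (is.null(x0)) {
        total_known <- FALSE
      } else if (total_known) {
        total <- rq_add(total, rq_mul(rq_int(y[i]), x0))
      }
    }
    rhs <- if (total_known) {
      ex_num(total)
    } else {
      sym_counter <- sym_counter + 1L
      ex_sym(paste0("c", sym_counter))
    }
    out[[length(out) + 1L]] <- list(
      kind = "conservation",
      lhs = e_sum(terms),
      rhs = rhs,
      coefficients = y,
      total = if (total_known) total else NULL,
      origin = b
    )
  }
  out
}
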