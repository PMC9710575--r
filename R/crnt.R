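# Chemical reaction network theory metrics: complexes, linkage classes,
# deficiency, and the polynomial/rational/mass-action classification of the
# assembled vector field.

complex_key <- function(index, coef) {
  if (!length(index)) return("0")
  ord <- order(index)
  paste(
    vapply(ord, function(k) paste0(index[k], ":", rq_to_str(coef[[k]])), character(1)),
    collapse = "+"
  )
}

#' Enumerate the complexes and reaction arrows of a network
#'
#' The complexes are the distinct reactant-side and product-side
#' compositions over all reactions, compared as exact multisets (2A and A
#' are distinct even though their reaction vectors are parallel); the empty
#' composition is the zero complex of inflow/outflow reactions. Each
#' reaction contributes one arrow, plus the reverse arrow when reversible.
#'
#' @param net a `reaction_network`.
#' @return `list(complexes = <named list of compositions>, arrows =
#'   <data.frame from/to of complex keys>)`.
#' @export
enumerate_complexes <- function(net) {
  complexes <- list()
  froms <- character(0)
  tos <- character(0)
  note <- function(st) {
    key <- complex_key(st$index, st$coef)
    if (is.null(complexes[[key]])) complexes[[key]] <<- st
    key
  }
  for (rx in net$reactions) {
    a <- note(rx$reactant_stoich)
    b <- note(rx$product_stoich)
    froms <- c(froms, a)
    tos <- c(tos, b)
    if (rx$reversible) {
      froms <- c(froms, b)
      tos <- c(tos, a)
    }
  }
  list(
    complexes = complexes,
    arrows = data.frame(from = froms, to = tos, stringsAsFactors = FALSE)
  )
}

#' Linkage classes of a complex graph
#'
#' Connected components of the undirected graph whose nodes are the
#' complexes and whose edges are the reaction arrows.
#'
#' @param complexes named list of complexes (from [enumerate_complexes()]).
#' @param arrows data.frame with columns `from`, `to` of complex keys.
#' @return a list of character vectors, one per linkage class.
#' @export
linkage_classes <- function(complexes, arrows) {
  keys <- names(complexes)
  if (!length(keys)) return(list())
  parent <- stats::setNames(keys, keys)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(arrows))) {
    a <- find(arrows$from[i])
    b <- find(arrows$to[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(keys, find, character(1))
  unname(split(keys, roots))
}

#' Deficiency of a reaction network
#'
#' The deficiency is `delta = c - l - s`: the number of complexes minus the
#' number of linkage classes minus the rank of the stoichiometric matrix. It
#' measures how independent the reaction vectors are, given the linkage
#' class structure, and is always nonnegative.
#'
#' @param net a `reaction_network`.
#' @return an object of class `deficiency_report` with fields
#'   `n_complexes`, `n_linkage_classes`, `rank`, `deficiency`.
#' @export
deficiency <- function(net) {
  en <- enumerate_complexes(net)
  lc <- linkage_classes(en$complexes, en$arrows)
  s <- network_rank(stoichiometric_matrix(net))
  d <- length(en$complexes) - length(lc) - s
  stopifnot(d >= 0)
  structure(
    list(
      n_complexes = length(en$complexes),
      n_linkage_classes = length(lc),
      rank = s,
      deficiency = d
    ),
    class = "deficiency_report"
  )
}

#' @export
print.deficiency_report <- function(x, ...) {
  cat(sprintf(
    "complexes c = %d, linkage classes l = %d, rank s = %d, deficiency = %d\n",
    x$n_complexes, x$n_linkage_classes, x$rank, x$deficiency
  ))
  invisible(x)
}

#' Mass-action test for the kinetic laws of a network
#'
#' A reaction passes when its kinetic law differs from regular mass-action
#' kinetics only by a constant factor: the symbolic quotient of the law by
#' `prod_i x_i^K[i,j]` (the reactant-order monomial) must be free of species
#' symbols and of time. "Constant" admits parameters, compartment sizes and
#' rational numbers. For a reversible reaction whose law is a net rate, the
#' law may instead split as a forward monomial matching the reactant orders
#' minus a reverse monomial matching the product orders. A law that does
#' not decompose counts as not mass-action (the conservative direction).
#'
#' @param net a `reaction_network`.
#' @param laws optional list of kinetic laws rewritten in canonical names
#'   (as inside an assembled `ode_system`); defaults to the raw laws with
#'   species under their SBML ids.
#' @param nm optional `name_map` matching `laws`.
#' @return `list(per_reaction = <logical vector>, model = <flag>)`; the
#'   model flag is the conjunction over reactions.
#' @export
is_mass_action <- function(net, laws = NULL, nm = NULL) {
  sp_ids <- vapply(net$species, `[[`, character(1), "id")
  if (is.null(laws)) {
    laws <- lapply(net$reactions, `[[`, "kinetic_law")
    species_names <- sp_ids
  } else {
    stopifnot(!is.null(nm))
    species_names <- unname(nm$species[sp_ids])
  }
  expo_of <- function(st) {
    v <- stats::setNames(
      vapply(st$coef, rq_to_double, numeric(1)),
      species_names[st$index]
    )
    v[v != 0]
  }
  same_expo <- function(a, b) {
    all_names <- union(names(a), names(b))
    va <- stats::setNames(numeric(length(all_names)), all_names)
    vb <- va
    va[names(a)] <- a
    vb[names(b)] <- b
    all(va == vb)
  }
  per <- vapply(seq_along(net$reactions), function(j) {
    rx <- net$reactions[[j]]
    law <- laws[[j]]
    if (is.null(law)) return(FALSE)
    want_fwd <- expo_of(rx$reactant_stoich)
    dec <- ex_monomial(law, species_names)
    if (!is.null(dec) && same_expo(dec, want_fwd)) return(TRUE)
    if (rx$reversible && law$t == "call" && law$op == "-" && length(law$args) == 2) {
      dfwd <- ex_monomial(law$args[[1]], species_names)
      drev <- ex_monomial(law$args[[2]], species_names)
      want_rev <- expo_of(rx$product_stoich)
      if (!is.null(dfwd) && !is.null(drev) &&
        same_expo(dfwd, want_fwd) && same_expo(drev, want_rev)) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  list(per_reaction = per, model = all(per))
}

#' Classify the assembled vector field and constraints
#'
#' Each right-hand side is classified as polynomial (a polynomial in the
#' state variables and time with coefficients rational in the parameters),
#' rational (a ratio of such polynomials) or other (e.g. exponentials of
#' state). The model-level mass-action flag holds when the vector field is
#' polynomial and every kinetic law passes the constant-factor mass-action
#' test.
#'
#' @param ode an `ode_system` from [assemble_odes()].
#' @param constraints optional list of constraints (assignment +
#'   conservation) whose right-hand sides are classified alongside.
#' @param ma result of [is_mass_action()] for the same network; optional.
#' @return an object of class `classification_report` with fields
#'   `vector_field_class`, `constraints_class`, `mass_action`.
#' @export
classify_vector_field <- function(ode, constraints = list(), ma = NULL) {
  statevars <- ode$variables
  eq_cls <- vapply(ode$equations, function(e) classify_expr(e, statevars), character(1))
  vf <- if (length(eq_cls)) do.call(cls_max, as.list(eq_cls)) else "polynomial"
  con_cls <- vapply(constraints, function(cn) {
    cls_max(classify_expr(cn$rhs, statevars), classify_expr(cn$lhs, statevars))
  }, character(1))
  cc <- if (length(con_cls)) do.call(cls_max, as.list(con_cls)) else "polynomial"
  mass_action <- if (is.null(ma)) NA else (ma$model && vf == "polynomial")
  structure(
    list(
      vector_field_class = vf,
      constraints_class = cc,
      mass_action = mass_action
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "vector field: %s; constraints: %s; mass-action: %s\n",
    x$vector_field_class, x$constraints_class, x$mass_action
  ))
  invisible(x)
}
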