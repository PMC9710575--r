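# Programmatic SBML fixture generation with ground truth known by
# construction: the generator writes kinetic laws from its own
# stoichiometric choices, so matrices and kinetics labels are true by
# construction, while deficiency and conservation-law counts come from a
# deliberately simple independent code path (string-keyed complexes,
# union-find, fraction-free integer elimination in doubles -- exact for the
# small integer matrices generated here).

# exact finite-decimal rendering of p/q (q must divide a power of 10)
finite_decimal_lex <- function(p, q) {
  k <- 0
  num <- p
  while (num %% q != 0) {
    if (k > 12) stop("denominator ", q, " has no finite decimal expansion")
    num <- num * 10
    k <- k + 1
  }
  digits <- num / q
  if (k == 0) return(sprintf("%.0f", digits))
  s <- sprintf(paste0("%0", k + 1, ".0f"), digits)
  paste0(substr(s, 1, nchar(s) - k), ".", substr(s, nchar(s) - k + 1, nchar(s)))
}

# ---- SBML document builder (plain text; layout is fixed so documents are
# byte-identical for identical inputs) ----

build_sbml_document <- function(model_id,
                                species,
                                parameters = list(),
                                reactions = list(),
                                assignment_rules = list(),
                                rate_rules = list(),
                                initial_assignments = list(),
                                compartment_id = "cell",
                                compartment_size = "1",
                                events_xml = NULL) {
  L <- character(0)
  put <- function(...) L <<- c(L, paste0(...))
  put("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  put("<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4\">")
  put("  <model id=\"", model_id, "\">")
  put("    <listOfCompartments>")
  put("      <compartment id=\"", compartment_id, "\" size=\"", compartment_size, "\" constant=\"true\"/>")
  put("    </listOfCompartments>")
  put("    <listOfSpecies>")
  for (s in species) {
    put(
      "      <species id=\"", s$id, "\" compartment=\"", compartment_id, "\"",
      if (!is.null(s$init)) paste0(" initialConcentration=\"", s$init, "\"") else "",
      if (isTRUE(s$boundary)) " boundaryCondition=\"true\"" else "",
      "/>"
    )
  }
  put("    </listOfSpecies>")
  if (length(parameters)) {
    put("    <listOfParameters>")
    for (p in parameters) {
      put(
        "      <parameter id=\"", p$id, "\"",
        if (!is.null(p$value)) paste0(" value=\"", p$value, "\"") else "",
        " constant=\"", if (isTRUE(p$constant) || is.null(p$constant)) "true" else "false", "\"/>"
      )
    }
    put("    </listOfParameters>")
  }
  if (length(initial_assignments)) {
    put("    <listOfInitialAssignments>")
    for (tgt in names(initial_assignments)) {
      put("      <initialAssignment symbol=\"", tgt, "\">")
      put("        ", ex_to_mathml(initial_assignments[[tgt]]))
      put("      </initialAssignment>")
    }
    put("    </listOfInitialAssignments>")
  }
  if (length(assignment_rules) || length(rate_rules)) {
    put("    <listOfRules>")
    for (tgt in names(assignment_rules)) {
      put("      <assignmentRule variable=\"", tgt, "\">")
      put("        ", ex_to_mathml(assignment_rules[[tgt]]))
      put("      </assignmentRule>")
    }
    for (tgt in names(rate_rules)) {
      put("      <rateRule variable=\"", tgt, "\">")
      put("        ", ex_to_mathml(rate_rules[[tgt]]))
      put("      </rateRule>")
    }
    put("    </listOfRules>")
  }
  put("    <listOfReactions>")
  for (rx in reactions) {
    put("      <reaction id=\"", rx$id, "\" reversible=\"", if (isTRUE(rx$reversible)) "true" else "false", "\">")
    side <- function(tag, refs) {
      if (!length(refs)) return(invisible())
      put("        <listOf", tag, ">")
      for (sr in refs) {
        put("          <speciesReference species=\"", sr$species, "\" stoichiometry=\"", sr$stoich, "\"/>")
      }
      put("        </listOf", tag, ">")
    }
    side("Reactants", rx$reactants)
    side("Products", rx$products)
    put("        <kineticLaw>")
    put("          ", ex_to_mathml(rx$law))
    if (length(rx$local_parameters)) {
      put("          <listOfParameters>")
      for (lp in rx$local_parameters) {
        put("            <parameter id=\"", lp$id, "\" value=\"", lp$value, "\"/>")
      }
      put("          </listOfParameters>")
    }
    put("        </kineticLaw>")
    put("      </reaction>")
  }
  put("    </listOfReactions>")
  if (!is.null(events_xml)) put(events_xml)
  put("  </model>")
  put("</sbml>")
  paste0(paste(L, collapse = "\n"), "\n")
}

# ---- independent simple-path ground truth ----

# fraction-free (Bareiss) rank of a small integer matrix in doubles; every
# intermediate is an integer determinant, far below 2^53 at fixture sizes
fixture_int_rank <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  r <- ncol(A)
  if (n == 0 || r == 0) return(0L)
  stopifnot(all(A == floor(A)))
  prev <- 1
  rank <- 0L
  cc <- 1L
  while (cc <= r && rank < n) {
    piv <- which(A[(rank + 1):n, cc] != 0)
    if (!length(piv)) {
      cc <- cc + 1L
      next
    }
    piv <- piv[1] + rank
    if (piv != rank + 1) A[c(piv, rank + 1), ] <- A[c(rank + 1, piv), ]
    p <- A[rank + 1, cc]
    if (rank + 2 <= n) {
      for (i in (rank + 2):n) {
        A[i, ] <- (p * A[i, ] - A[i, cc] * A[rank + 1, ]) / prev
        stopifnot(all(A[i, ] == floor(A[i, ])))
      }
    }
    prev <- p
    rank <- rank + 1L
    cc <- cc + 1L
  }
  rank
}

# complexes / linkage classes / deficiency from plain reactant and product
# coefficient matrices (columns = reactions)
fixture_deficiency_oracle <- function(R, P, reversible = rep(FALSE, ncol(R))) {
  key <- function(v) {
    nz <- which(v != 0)
    if (!length(nz)) return("0")
    paste(paste0(nz, ":", v[nz]), collapse = "+")
  }
  r <- ncol(R)
  froms <- character(0)
  tos <- character(0)
  keys <- character(0)
  for (j in seq_len(r)) {
    a <- key(R[, j])
    b <- key(P[, j])
    keys <- union(keys, c(a, b))
    froms <- c(froms, a)
    tos <- c(tos, b)
    if (reversible[j]) {
      froms <- c(froms, b)
      tos <- c(tos, a)
    }
  }
  parent <- stats::setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(froms)) {
    a <- find(match(froms[e], keys))
    b <- find(match(tos[e], keys))
    if (a != b) parent[a] <- b
  }
  n_link <- length(unique(vapply(seq_along(keys), find, numeric(1))))
  s <- fixture_int_rank(P - R)
  list(
    n_complexes = length(keys),
    n_linkage_classes = n_link,
    rank = s,
    deficiency = length(keys) - n_link - s
  )
}

# ---- seeded random fixture generation ----

#' Specification for a generated SBML fixture
#'
#' @param n_species number of species (>= 1).
#' @param n_reactions number of reactions (>= 1).
#' @param kinetics `"mass-action"`, `"michaelis-menten"` or `"mixed"`.
#' @param reversible_fraction proportion of mass-action reactions emitted
#'   as reversible (net-rate law), in `[0, 1]`.
#' @param include_boundary mark the first species as a boundary species.
#' @param include_rules add an assignment-rule species and a parameter
#'   initial assignment.
#' @param seed RNG seed; identical specs yield byte-identical documents.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_species, n_reactions,
                         kinetics = c("mass-action", "michaelis-menten", "mixed"),
                         reversible_fraction = 0,
                         include_boundary = FALSE,
                         include_rules = FALSE,
                         seed = 1L) {
  kinetics <- match.arg(kinetics)
  stopifnot(n_species >= 1, n_reactions >= 1)
  stopifnot(reversible_fraction >= 0, reversible_fraction <= 1)
  structure(
    list(
      n_species = as.integer(n_species),
      n_reactions = as.integer(n_reactions),
      kinetics = kinetics,
      reversible_fraction = reversible_fraction,
      include_boundary = isTRUE(include_boundary),
      include_rules = isTRUE(include_rules),
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate an SBML document with known ground truth
#'
#' Builds a random reaction network according to the spec and writes it as
#' SBML Level 2, together with a manifest holding the ground truth the
#' generator knows by construction: the stoichiometric and kinetic-order
#' matrices, per-reaction kinetics labels, the expected deficiency,
#' conservation-law count and classification flags. Rate constants and
#' initial concentrations are exact finite-decimal rationals, never binary
#' floats.
#'
#' @param spec a [fixture_spec()].
#' @return `list(sbml = <XML text>, manifest = <ground-truth list>)`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_species
    r <- spec$n_reactions
    sp_ids <- paste0("S", seq_len(n))

    rand_rate <- function() {
      p <- sample(1:9, 1)
      q <- sample(c(1, 2, 4, 5, 8, 10), 1)
      finite_decimal_lex(p, q)
    }

    labels <- character(r)
    reversible <- logical(r)
    R <- matrix(0, n, r)
    P <- matrix(0, n, r)
    parameters <- list()
    reactions <- list()

    for (j in seq_len(r)) {
      lab <- switch(spec$kinetics,
        "mass-action" = "mass-action",
        "michaelis-menten" = "michaelis-menten",
        "mixed" = sample(c("mass-action", "michaelis-menten"), 1)
      )
      labels[j] <- lab
      if (lab == "michaelis-menten") {
        sub <- sample.int(n, 1)
        cand <- setdiff(seq_len(n), sub)
        prod <- if (length(cand)) cand[sample.int(length(cand), 1)] else sub
        R[sub, j] <- 1
        if (prod != sub) P[prod, j] <- 1 else P[prod, j] <- 2
        vid <- paste0("V", j)
        kid <- paste0("K", j)
        parameters <- c(parameters,
          list(list(id = vid, value = rand_rate()), list(id = kid, value = rand_rate()))
        )
        law <- e_div(
          e_mul(ex_sym(vid), ex_sym(sp_ids[sub])),
          ex_call("+", list(ex_sym(kid), ex_sym(sp_ids[sub])))
        )
        reactions[[j]] <- list(
          id = paste0("R", j), reversible = FALSE,
          reactants = list(list(species = sp_ids[sub], stoich = "1")),
          products = list(list(species = sp_ids[prod], stoich = as.character(P[prod, j]))),
          law = law, local_parameters = list()
        )
      } else {
        for (attempt in 1:20) {
          nr <- sample.int(min(2L, n), 1)
          np <- sample.int(min(2L, n), 1)
          rsp <- sample.int(n, nr)
          psp <- sample.int(n, np)
          rv <- numeric(n)
          pv <- numeric(n)
          rv[rsp] <- sample(1:2, nr, replace = TRUE)
          pv[psp] <- sample(1:2, np, replace = TRUE)
          if (any(rv != pv)) break
        }
        R[, j] <- rv
        P[, j] <- pv
        rev <- stats::runif(1) < spec$reversible_fraction
        reversible[j] <- rev
        kf <- paste0("k", j, "f")
        parameters <- c(parameters, list(list(id = kf, value = rand_rate())))
        mono <- function(cid, v) {
          factors <- list(ex_sym(cid))
          for (i in which(v != 0)) {
            factors[[length(factors) + 1L]] <- if (v[i] == 1) {
              ex_sym(sp_ids[i])
            } else {
              e_pow(ex_sym(sp_ids[i]), ex_num(v[i]))
            }
          }
          e_prod(factors)
        }
        law <- if (rev) {
          kr <- paste0("k", j, "r")
          parameters <- c(parameters, list(list(id = kr, value = rand_rate())))
          e_sub(mono(kf, rv), mono(kr, pv))
        } else {
          mono(kf, rv)
        }
        srefs <- function(v) {
          lapply(which(v != 0), function(i) list(species = sp_ids[i], stoich = as.character(v[i])))
        }
        reactions[[j]] <- list(
          id = paste0("R", j), reversible = rev,
          reactants = srefs(rv), products = srefs(pv),
          law = law, local_parameters = list()
        )
      }
    }

    boundary <- rep(FALSE, n)
    if (spec$include_boundary) boundary[1] <- TRUE
    species <- lapply(seq_len(n), function(i) {
      list(
        id = sp_ids[i],
        init = finite_decimal_lex(sample(0:5, 1), sample(c(1, 2, 4, 5), 1)),
        boundary = boundary[i]
      )
    })

    assignment_rules <- list()
    initial_assignments <- list()
    asg_flags <- rep(FALSE, n)
    if (spec$include_rules) {
      species <- c(species, list(list(id = "Zass", init = NULL, boundary = FALSE)))
      rhs <- if (n >= 2) ex_call("+", list(ex_sym(sp_ids[1]), ex_sym(sp_ids[2]))) else ex_sym(sp_ids[1])
      assignment_rules[["Zass"]] <- rhs
      initial_assignments[[parameters[[1]]$id]] <- ex_num(rq_raw(bi_from_num(3), bi_from_num(2)))
      R <- rbind(R, 0)
      P <- rbind(P, 0)
      boundary <- c(boundary, FALSE)
      asg_flags <- c(asg_flags, TRUE)
    }

    sbml <- build_sbml_document(
      model_id = paste0("fixture_seed", spec$seed),
      species = species,
      parameters = parameters,
      reactions = reactions,
      assignment_rules = assignment_rules,
      initial_assignments = initial_assignments
    )

    S <- P - R
    dyn <- !boundary & !asg_flags
    orc <- fixture_deficiency_oracle(R, P, reversible)
    S_dyn <- S[dyn, , drop = FALSE]
    n_cons <- sum(dyn) - fixture_int_rank(S_dyn)
    all_ma <- all(labels == "mass-action")
    # a rational law shapes the vector field only if it reaches some ODE:
    # a reaction all of whose net changes hit boundary species drops out
    mm_alive <- any(vapply(seq_len(r), function(j) {
      labels[j] == "michaelis-menten" && any(S_dyn[, j] != 0)
    }, logical(1)))

    manifest <- list(
      species_ids = vapply(species, `[[`, character(1), "id"),
      boundary = boundary,
      assignment_species = asg_flags,
      S = S,
      K = R,
      laws = lapply(reactions, `[[`, "law"),
      param_values = stats::setNames(
        vapply(parameters, `[[`, character(1), "value"),
        vapply(parameters, `[[`, character(1), "id")
      ),
      init_values = stats::setNames(
        vapply(species, function(s) if (is.null(s$init)) NA_character_ else s$init, character(1)),
        vapply(species, `[[`, character(1), "id")
      ),
      labels = labels,
      reversible = reversible,
      expected_deficiency = orc$deficiency,
      expected_n_complexes = orc$n_complexes,
      expected_n_linkage_classes = orc$n_linkage_classes,
      expected_rank = orc$rank,
      expected_n_conservation = n_cons,
      expected_mass_action = all_ma,
      expected_vf_class = if (mm_alive) "rational" else "polynomial"
    )
    list(sbml = sbml, manifest = manifest)
  })
}

#' Canonical toy networks with hand-checked ground truth
#'
#' Five small named networks covering the interesting structural cases:
#' `iso` (A = B interconversion, deficiency 0, one conservation law),
#' `bind` (A + B = C binding, deficiency 0, two conservation laws), `def1`
#' (A -> B alongside 2A -> 2B, the classic deficiency-one pair), `inflow`
#' (0 -> A -> 0 open system, no conservation law) and `mm` (one
#' Michaelis-Menten conversion, rational non-mass-action kinetics).
#'
#' @return named list; each element is `list(sbml, manifest)` as in
#'   [generate_fixture()].
#' @export
named_toys <- function() {
  two_sp <- function(a = "A", b = "B") list(
    list(id = a, init = "2", boundary = FALSE),
    list(id = b, init = "0.5", boundary = FALSE)
  )
  mk <- function(id, species, parameters, reactions, R, P, reversible, labels) {
    sbml <- build_sbml_document(id, species, parameters, reactions)
    n <- length(species)
    S <- P - R
    dyn <- rep(TRUE, n)
    orc <- fixture_deficiency_oracle(R, P, reversible)
    all_ma <- all(labels == "mass-action")
    list(
      sbml = sbml,
      manifest = list(
        species_ids = vapply(species, `[[`, character(1), "id"),
        boundary = rep(FALSE, n),
        assignment_species = rep(FALSE, n),
        S = S, K = R,
        laws = lapply(reactions, `[[`, "law"),
        param_values = stats::setNames(
          vapply(parameters, `[[`, character(1), "value"),
          vapply(parameters, `[[`, character(1), "id")
        ),
        labels = labels, reversible = reversible,
        expected_deficiency = orc$deficiency,
        expected_n_complexes = orc$n_complexes,
        expected_n_linkage_classes = orc$n_linkage_classes,
        expected_rank = orc$rank,
        expected_n_conservation = n - fixture_int_rank(S),
        expected_mass_action = all_ma,
        expected_vf_class = if (all_ma) "polynomial" else "rational"
      )
    )
  }

  toys <- list()

  toys$iso <- mk(
    "toy_iso", two_sp(),
    list(list(id = "kf", value = "0.5"), list(id = "kr", value = "2")),
    list(list(
      id = "R1", reversible = TRUE,
      reactants = list(list(species = "A", stoich = "1")),
      products = list(list(species = "B", stoich = "1")),
      law = e_sub(e_mul(ex_sym("kf"), ex_sym("A")), e_mul(ex_sym("kr"), ex_sym("B"))),
      local_parameters = list()
    )),
    R = matrix(c(1, 0), 2, 1), P = matrix(c(0, 1), 2, 1),
    reversible = TRUE, labels = "mass-action"
  )

  toys$bind <- mk(
    "toy_bind",
    list(
      list(id = "A", init = "1", boundary = FALSE),
      list(id = "B", init = "2", boundary = FALSE),
      list(id = "C", init = "0", boundary = FALSE)
    ),
    list(list(id = "kon", value = "4"), list(id = "koff", value = "0.25")),
    list(list(
      id = "R1", reversible = TRUE,
      reactants = list(list(species = "A", stoich = "1"), list(species = "B", stoich = "1")),
      products = list(list(species = "C", stoich = "1")),
      law = e_sub(
        e_mul(ex_sym("kon"), ex_sym("A"), ex_sym("B")),
        e_mul(ex_sym("koff"), ex_sym("C"))
      ),
      local_parameters = list()
    )),
    R = matrix(c(1, 1, 0), 3, 1), P = matrix(c(0, 0, 1), 3, 1),
    reversible = TRUE, labels = "mass-action"
  )

  toys$def1 <- mk(
    "toy_def1", two_sp(),
    list(list(id = "k1", value = "1"), list(id = "k2", value = "0.1")),
    list(
      list(
        id = "R1", reversible = FALSE,
        reactants = list(list(species = "A", stoich = "1")),
        products = list(list(species = "B", stoich = "1")),
        law = e_mul(ex_sym("k1"), ex_sym("A")),
        local_parameters = list()
      ),
      list(
        id = "R2", reversible = FALSE,
        reactants = list(list(species = "A", stoich = "2")),
        products = list(list(species = "B", stoich = "2")),
        law = e_mul(ex_sym("k2"), e_pow(ex_sym("A"), ex_num(2))),
        local_parameters = list()
      )
    ),
    R = matrix(c(1, 0, 2, 0), 2, 2), P = matrix(c(0, 1, 0, 2), 2, 2),
    reversible = c(FALSE, FALSE), labels = c("mass-action", "mass-action")
  )

  toys$inflow <- mk(
    "toy_inflow",
    list(list(id = "A", init = "0", boundary = FALSE)),
    list(list(id = "kin", value = "2.5"), list(id = "kout", value = "0.5")),
    list(
      list(
        id = "R1", reversible = FALSE,
        reactants = list(),
        products = list(list(species = "A", stoich = "1")),
        law = ex_sym("kin"),
        local_parameters = list()
      ),
      list(
        id = "R2", reversible = FALSE,
        reactants = list(list(species = "A", stoich = "1")),
        products = list(),
        law = e_mul(ex_sym("kout"), ex_sym("A")),
        local_parameters = list()
      )
    ),
    R = matrix(c(0, 1), 1, 2), P = matrix(c(1, 0), 1, 2),
    reversible = c(FALSE, FALSE), labels = c("mass-action", "mass-action")
  )

  toys$mm <- mk(
    "toy_mm", two_sp("S", "P"),
    list(list(id = "Vmax", value = "1.5"), list(id = "Km", value = "0.8")),
    list(list(
      id = "R1", reversible = FALSE,
      reactants = list(list(species = "S", stoich = "1")),
      products = list(list(species = "P", stoich = "1")),
      law = e_div(
        e_mul(ex_sym("Vmax"), ex_sym("S")),
        ex_call("+", list(ex_sym("Km"), ex_sym("S")))
      ),
      local_parameters = list()
    )),
    R = matrix(c(1, 0), 2, 1), P = matrix(c(0, 1), 2, 1),
    reversible = FALSE, labels = "michaelis-menten"
  )

  toys
}
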