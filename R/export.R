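# Serialization of a complete dataset into computer-algebra dialects
# (Maple, Reduce, SageMath, LaTeX) plus a canonical JSON manifest, and the
# SageMath round-trip parser used to verify exports.
#
# Exactness is preserved end-to-end: every numeric literal in the rendered
# text is an integer or a quotient p/q; no decimal point ever appears in a
# Maple/Reduce/SageMath export.

eq_names <- function(ds) names(ds$ode$equations)

dataset_sections <- function(ds) {
  nm <- ds$name_map
  list(
    vars = ds$ode$variables,
    dynvars = eq_names(ds),
    params = unname(nm$parameters),
    name_pairs = rbind(
      data.frame(math = unname(nm$species), sbml = names(nm$species), stringsAsFactors = FALSE),
      data.frame(math = unname(nm$parameters), sbml = names(nm$parameters), stringsAsFactors = FALSE)
    )
  )
}

#' Render a dataset in a computer-algebra dialect
#'
#' Produces a deterministic plain-text document containing the variable
#' list, the ODE right-hand sides, exact rational parameter and initial
#' values, the formal constraints, the stoichiometric and kinetic matrices,
#' the deficiency report, the classification flags and the name map (as
#' comments). Rationals are rendered as quotients (`1/10`), never as
#' floating literals.
#'
#' @param ds an `ode_dataset` from [sbml_to_ode()].
#' @param dialect one of `"maple"`, `"reduce"`, `"sagemath"`, `"latex"`,
#'   `"manifest"` (JSON).
#' @return an object of class `export_document`: `list(dialect, text)`.
#' @export
render_dataset <- function(ds, dialect) {
  if (!dialect %in% c("maple", "reduce", "sagemath", "latex", "manifest")) {
    stop("unknown dialect: ", dialect)
  }
  switch(dialect,
    maple = render_cas(ds, "maple"),
    reduce = render_cas(ds, "reduce"),
    sagemath = render_cas(ds, "sagemath"),
    latex = render_latex(ds),
    manifest = render_manifest(ds)
  )
}

#' @export
print.export_document <- function(x, ...) {
  cat(x$text)
  invisible(x)
}

render_cas <- function(ds, dialect) {
  cmt <- if (dialect == "reduce") "% " else "# "
  assign_op <- if (dialect == "sagemath") " = " else " := "
  eol <- switch(dialect, maple = ":", reduce = "$", sagemath = "")
  sec <- dataset_sections(ds)
  rend <- function(e) ex_render(e, dialect)
  qstr <- function(q) rq_to_str(q)

  lines <- character(0)
  put <- function(...) lines <<- c(lines, paste0(...))
  stmt <- function(lhs, rhs) put(lhs, assign_op, rhs, eol)

  put(cmt, ds$provenance$source, " : ", dialect, " export (",
      ds$provenance$tool, " ", ds$provenance$tool_version, ")")
  put(cmt, "name map (mathematical name = original SBML id):")
  for (i in seq_len(nrow(sec$name_pairs))) {
    put(cmt, "  ", sec$name_pairs$math[i], " = ", sec$name_pairs$sbml[i])
  }

  list_open <- if (dialect == "reduce") "{" else "["
  list_close <- if (dialect == "reduce") "}" else "]"
  stmt("vars", paste0(list_open, paste(sec$vars, collapse = ", "), list_close))
  stmt("params", paste0(list_open, paste(sec$params, collapse = ", "), list_close))

  put(cmt, "exact rational parameter values")
  for (k in names(ds$parameter_values)) {
    stmt(k, qstr(ds$parameter_values[[k]]))
  }
  put(cmt, "exact rational initial values (concentrations)")
  for (x in names(ds$initial_values)) {
    stmt(paste0(x, "_init"), qstr(ds$initial_values[[x]]))
  }

  put(cmt, "ODE right-hand sides: d<var>/dt = f_<var>")
  for (v in sec$dynvars) {
    stmt(paste0("f_", v), rend(ds$ode$equations[[v]]))
  }

  if (length(ds$constraints)) {
    put(cmt, "formal constraints (species assignments and conservation laws)")
    for (i in seq_along(ds$constraints)) {
      cn <- ds$constraints[[i]]
      rel <- if (dialect == "sagemath") " == " else " = "
      stmt(paste0("constraint_", i),
           paste0(rend(cn$lhs), rel, rend(cn$rhs)))
    }
  }

  mat_str <- function(M) {
    C <- rmat_to_char(M)
    rows <- apply(C, 1, function(rw) paste(rw, collapse = ", "))
    switch(dialect,
      maple = paste0("Matrix([", paste0("[", rows, "]", collapse = ", "), "])"),
      reduce = paste0("mat(", paste0("(", rows, ")", collapse = ", "), ")"),
      sagemath = paste0("matrix(QQ, [", paste0("[", rows, "]", collapse = ", "), "])")
    )
  }
  put(cmt, "stoichiometric matrix S (species x reactions) and kinetic matrix K")
  stmt("S", mat_str(ds$stoichiometric))
  stmt("K", mat_str(ds$kinetic))

  put(cmt, "deficiency = complexes - linkage classes - rank")
  stmt("n_complexes", ds$deficiency$n_complexes)
  stmt("n_linkage_classes", ds$deficiency$n_linkage_classes)
  stmt("s_rank", ds$deficiency$rank)
  stmt("deficiency", ds$deficiency$deficiency)

  put(cmt, "classification")
  qq <- function(s) paste0("\"", s, "\"")
  stmt("vector_field_class", qq(ds$classification$vector_field_class))
  stmt("constraints_class", qq(ds$classification$constraints_class))
  bool <- function(b) {
    if (dialect == "sagemath") (if (b) "True" else "False") else (if (b) "true" else "false")
  }
  stmt("mass_action", bool(isTRUE(ds$classification$mass_action)))
  stmt("autonomous", bool(isTRUE(ds$ode$autonomous)))

  structure(list(dialect = dialect, text = paste0(paste(lines, collapse = "\n"), "\n")),
            class = "export_document")
}

render_latex <- function(ds) {
  sec <- dataset_sections(ds)
  rend <- function(e) ex_render(e, "latex")
  lsym <- function(v) {
    m <- regmatches(v, regexec("^([A-Za-z]+)([0-9]+)$", v))[[1]]
    if (length(m) == 3) paste0(m[2], "_{", m[3], "}") else v
  }
  lines <- character(0)
  put <- function(...) lines <<- c(lines, paste0(...))
  put("% ", ds$provenance$source, " : LaTeX export (",
      ds$provenance$tool, " ", ds$provenance$tool_version, ")")
  put("% name map: ",
      paste(sprintf("%s = %s", sec$name_pairs$math, sec$name_pairs$sbml), collapse = "; "))
  put("\\begin{align*}")
  for (v in sec$dynvars) {
    put("  \\dot{", lsym(v), "} &= ", rend(ds$ode$equations[[v]]), " \\\\")
  }
  put("\\end{align*}")
  if (length(ds$parameter_values)) {
    put("\\begin{align*}")
    for (k in names(ds$parameter_values)) {
      put("  ", lsym(k), " &= ", rend(ex_num(ds$parameter_values[[k]])), " \\\\")
    }
    put("\\end{align*}")
  }
  if (length(ds$constraints)) {
    put("\\begin{align*}")
    for (cn in ds$constraints) {
      put("  ", rend(cn$lhs), " &= ", rend(cn$rhs), " \\\\")
    }
    put("\\end{align*}")
  }
  mat_tex <- function(M) {
    C <- rmat_to_char(M)
    Ct <- matrix(vapply(seq_along(C), function(i) {
      e <- sage_parse_expr(C[[i]])
      ex_render(e, "latex")
    }, character(1)), nrow(C), ncol(C))
    rows <- apply(Ct, 1, function(rw) paste(rw, collapse = " & "))
    paste0("\\begin{pmatrix} ", paste(rows, collapse = " \\\\ "), " \\end{pmatrix}")
  }
  put("\\[ S = ", mat_tex(ds$stoichiometric), " \\qquad K = ", mat_tex(ds$kinetic), " \\]")
  put("\\[ c = ", ds$deficiency$n_complexes,
      ", \\quad \\ell = ", ds$deficiency$n_linkage_classes,
      ", \\quad s = ", ds$deficiency$rank,
      ", \\quad \\delta = c - \\ell - s = ", ds$deficiency$deficiency, " \\]")
  structure(list(dialect = "latex", text = paste0(paste(lines, collapse = "\n"), "\n")),
            class = "export_document")
}

dataset_manifest_list <- function(ds) {
  nm <- ds$name_map
  net <- ds$network
  con_laws <- lapply(Filter(function(cn) cn$kind == "conservation", ds$constraints), function(cn) {
    list(
      coefficients = as.integer(cn$coefficients),
      variables = ds$dynamic_variables,
      total = if (is.null(cn$total)) NULL else rq_to_str(cn$total)
    )
  })
  list(
    tool = ds$provenance$tool,
    tool_version = ds$provenance$tool_version,
    source = ds$provenance$source,
    model_id = if (is.null(ds$model_id) || is.na(ds$model_id)) NULL else ds$model_id,
    divide_by_compartment = ds$provenance$divide_by_compartment,
    species = lapply(seq_along(net$species), function(i) {
      s <- net$species[[i]]
      list(
        id = s$id, name = unname(nm$species[[s$id]]),
        boundary = s$boundary, assignment_rule = s$has_assignment_rule,
        rate_rule = s$has_rate_rule, compartment = s$compartment
      )
    }),
    parameters = lapply(net$parameters, function(p) {
      list(
        id = p$id, name = unname(nm$parameters[[p$id]]),
        value = if (is.null(p$value)) NULL else rq_to_str(p$value),
        origin = p$origin
      )
    }),
    reactions = lapply(seq_along(net$reactions), function(j) {
      rx <- net$reactions[[j]]
      list(
        id = rx$id, reversible = rx$reversible,
        mass_action = ds$mass_action_per_reaction[j]
      )
    }),
    variables = ds$ode$variables,
    equations = stats::setNames(
      lapply(eq_names(ds), function(v) ex_render(ds$ode$equations[[v]], "plain")),
      eq_names(ds)
    ),
    parameter_values = stats::setNames(
      lapply(names(ds$parameter_values), function(k) rq_to_str(ds$parameter_values[[k]])),
      names(ds$parameter_values)
    ),
    initial_values = stats::setNames(
      lapply(names(ds$initial_values), function(x) rq_to_str(ds$initial_values[[x]])),
      names(ds$initial_values)
    ),
    constraints = lapply(ds$constraints, function(cn) {
      list(
        kind = cn$kind,
        lhs = ex_render(cn$lhs, "plain"),
        rhs = ex_render(cn$rhs, "plain")
      )
    }),
    conservation_laws = con_laws,
    stoichiometric_matrix = rmat_to_char(ds$stoichiometric),
    kinetic_matrix = rmat_to_char(ds$kinetic),
    deficiency = list(
      n_complexes = ds$deficiency$n_complexes,
      n_linkage_classes = ds$deficiency$n_linkage_classes,
      rank = ds$deficiency$rank,
      deficiency = ds$deficiency$deficiency
    ),
    classification = list(
      vector_field_class = ds$classification$vector_field_class,
      constraints_class = ds$classification$constraints_class,
      mass_action = isTRUE(ds$classification$mass_action)
    ),
    autonomous = ds$ode$autonomous
  )
}

render_manifest <- function(ds) {
  txt <- jsonlite::toJSON(
    dataset_manifest_list(ds),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  structure(list(dialect = "manifest", text = paste0(as.character(txt), "\n")),
            class = "export_document")
}

#' Validate a dataset manifest against the expected schema
#'
#' Structural validation of the JSON manifest written next to the dialect
#' exports: all required fields present with the right types and mutually
#' consistent dimensions. The schema itself ships with the package
#' (`inst/extdata/manifest-schema.json`).
#'
#' @param json manifest text (or parsed list).
#' @return TRUE invisibly; otherwise an error describing the violation.
#' @export
validate_manifest <- function(json) {
  m <- if (is.character(json)) jsonlite::fromJSON(json, simplifyVector = FALSE) else json
  need <- c(
    "tool", "tool_version", "source", "species", "parameters", "reactions",
    "variables", "equations", "parameter_values", "initial_values",
    "constraints", "conservation_laws", "stoichiometric_matrix",
    "kinetic_matrix", "deficiency", "classification", "autonomous"
  )
  missing <- setdiff(need, names(m))
  if (length(missing)) stop("manifest missing fields: ", paste(missing, collapse = ", "))
  for (f in c("n_complexes", "n_linkage_classes", "rank", "deficiency")) {
    v <- m$deficiency[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0) stop("manifest deficiency field invalid: ", f)
  }
  if (m$deficiency$deficiency !=
      m$deficiency$n_complexes - m$deficiency$n_linkage_classes - m$deficiency$rank) {
    stop("manifest deficiency fields inconsistent")
  }
  if (!is.character(m$classification$vector_field_class) ||
      !m$classification$vector_field_class %in% c("polynomial", "rational", "other")) {
    stop("manifest classification invalid")
  }
  n_sp <- length(m$species)
  Smat <- m$stoichiometric_matrix
  if (n_sp > 0 && length(Smat) != n_sp) stop("manifest stoichiometric matrix row count mismatch")
  if (length(m$variables) != n_sp) stop("manifest variable count mismatch")
  for (entry in Smat) {
    for (cell in unlist(entry)) {
      if (grepl("\\.", cell)) stop("manifest matrix contains a floating literal: ", cell)
    }
  }
  invisible(TRUE)
}

#' Parse a SageMath export back into a partial dataset
#'
#' Round-trip verification aid: recovers the variable list, parameter
#' values, ODE right-hand sides and the two matrices from the text written
#' by `render_dataset(ds, "sagemath")`. Raises a parse error on malformed
#' or truncated input.
#'
#' @param text the SageMath export text.
#' @return `list(variables, params, parameter_values, equations, S, K,
#'   deficiency)` with expression trees and exact rational matrices.
#' @export
parse_sagemath_export <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stop("empty or invalid SageMath export")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*\\S)\\s*$", ln))[[1]]
    if (length(m) != 3) stop("malformed line in SageMath export: ", ln)
    kv[[m[2]]] <- m[3]
  }
  for (req in c("vars", "S", "K")) {
    if (is.null(kv[[req]])) stop("SageMath export missing '", req, "'")
  }
  parse_list <- function(s) {
    s <- sub("^\\[", "", sub("\\]$", "", trimws(s)))
    if (!nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  parse_matrix <- function(s) {
    body <- regmatches(s, regexec("^matrix\\(QQ, \\[(.*)\\]\\)$", s))[[1]]
    if (length(body) != 2) stop("malformed matrix in SageMath export: ", s)
    inner <- body[2]
    if (!nzchar(trimws(inner))) return(rmat_new(0, 0))
    rows <- strsplit(gsub("^\\[|\\]$", "", inner), "\\],\\s*\\[")[[1]]
    cells <- lapply(rows, function(rw) {
      if (!nzchar(trimws(rw))) return(list())
      lapply(trimws(strsplit(rw, ",", fixed = TRUE)[[1]]), function(cell) {
        res <- eval_constant(sage_parse_expr(cell), list())
        if (res$irrational) stop("non-rational matrix entry: ", cell)
        res$value
      })
    })
    n <- length(cells)
    r <- length(cells[[1]])
    M <- rmat_new(n, r)
    for (i in seq_len(n)) {
      if (length(cells[[i]]) != r) stop("ragged matrix in SageMath export")
      for (j in seq_len(r)) M[[i, j]] <- cells[[i]][[j]]
    }
    M
  }
  vars <- parse_list(kv$vars)
  params <- if (is.null(kv$params)) character(0) else parse_list(kv$params)
  parameter_values <- list()
  for (k in params) {
    if (!is.null(kv[[k]])) {
      res <- eval_constant(sage_parse_expr(kv[[k]]), list())
      if (!res$irrational) parameter_values[[k]] <- res$value
    }
  }
  equations <- list()
  for (nmk in names(kv)) {
    if (grepl("^f_x[0-9]+$", nmk)) {
      equations[[sub("^f_", "", nmk)]] <- sage_parse_expr(kv[[nmk]])
    }
  }
  defic <- list()
  for (f in c("n_complexes", "n_linkage_classes", "s_rank", "deficiency")) {
    if (!is.null(kv[[f]])) defic[[f]] <- as.integer(kv[[f]])
  }
  list(
    variables = vars,
    params = params,
    parameter_values = parameter_values,
    equations = equations,
    S = parse_matrix(kv$S),
    K = parse_matrix(kv$K),
    deficiency = defic
  )
}
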