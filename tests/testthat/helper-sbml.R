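# Hand-written SBML documents (kept independent of the package's own
# document builder) and small oracles used across the test files.

sbml_wrap <- function(model_body, level = "2", version = "4",
                      ns = "http://www.sbml.org/sbml/level2/version4") {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"", ns, "\" level=\"", level, "\" version=\"", version, "\">\n",
    "<model id=\"m\">\n", model_body, "</model>\n</sbml>\n"
  )
}

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

math <- function(inner) paste0("<math xmlns=\"", MATHML_NS, "\">", inner, "</math>")

doc_minimal <- function(k1_value = "0.1") {
  sbml_wrap(paste0(
    "<listOfCompartments><compartment id=\"c\" size=\"1\"/></listOfCompartments>\n",
    "<listOfSpecies>\n",
    "<species id=\"A\" compartment=\"c\" initialConcentration=\"1\"/>\n",
    "<species id=\"B\" compartment=\"c\" initialConcentration=\"0\"/>\n",
    "</listOfSpecies>\n",
    "<listOfParameters><parameter id=\"k1\" value=\"", k1_value, "\"/></listOfParameters>\n",
    "<listOfReactions>\n",
    "<reaction id=\"R1\" reversible=\"false\">\n",
    "<listOfReactants><speciesReference species=\"A\"/></listOfReactants>\n",
    "<listOfProducts><speciesReference species=\"B\"/></listOfProducts>\n",
    "<kineticLaw>", math("<apply><times/><ci>k1</ci><ci>A</ci></apply>"), "</kineticLaw>\n",
    "</reaction>\n</listOfReactions>\n"
  ))
}

doc_with_events <- function() {
  sub("</model>", paste0(
    "<listOfEvents><event id=\"e1\"><trigger>",
    math("<apply><times/><ci>A</ci><ci>A</ci></apply>"),
    "</trigger></event></listOfEvents></model>"
  ), doc_minimal(), fixed = TRUE)
}

doc_param_rate_rule <- function() {
  body <- paste0(
    "<listOfRules><rateRule variable=\"k2\">",
    math("<cn type=\"integer\">1</cn>"),
    "</rateRule></listOfRules>\n"
  )
  d <- doc_minimal()
  d <- sub("</listOfParameters>",
           "<parameter id=\"k2\" value=\"1\" constant=\"false\"/></listOfParameters>", d, fixed = TRUE)
  sub("<listOfReactions>", paste0(body, "<listOfReactions>"), d, fixed = TRUE)
}

doc_irrational_param <- function() {
  d <- doc_minimal()
  d <- sub("</listOfParameters>",
           "<parameter id=\"p\" value=\"1\"/></listOfParameters>", d, fixed = TRUE)
  sub("<listOfReactions>", paste0(
    "<listOfInitialAssignments><initialAssignment symbol=\"p\">",
    math("<apply><exp/><cn type=\"integer\">1</cn></apply>"),
    "</initialAssignment></listOfInitialAssignments>\n<listOfReactions>"
  ), d, fixed = TRUE)
}

doc_function_defs <- function() {
  d <- doc_minimal()
  sub("<listOfCompartments>", paste0(
    "<listOfFunctionDefinitions><functionDefinition id=\"f\">",
    math(paste0(
      "<lambda><bvar><ci>a</ci></bvar><bvar><ci>b</ci></bvar>",
      "<apply><times/><ci>a</ci><ci>b</ci></apply></lambda>"
    )),
    "</functionDefinition></listOfFunctionDefinitions>\n<listOfCompartments>"
  ), d, fixed = TRUE)
}

# two reactions, each with a local parameter "k" shadowing the global "k"
doc_local_shadow <- function() {
  law <- function() paste0(
    "<kineticLaw>", math("<apply><times/><ci>k</ci><ci>A</ci></apply>"),
    "<listOfParameters><parameter id=\"k\" value=\"2\"/></listOfParameters></kineticLaw>"
  )
  sbml_wrap(paste0(
    "<listOfCompartments><compartment id=\"c\" size=\"1\"/></listOfCompartments>\n",
    "<listOfSpecies>\n",
    "<species id=\"A\" compartment=\"c\" initialConcentration=\"1\"/>\n",
    "<species id=\"B\" compartment=\"c\" initialConcentration=\"0\"/>\n",
    "</listOfSpecies>\n",
    "<listOfParameters><parameter id=\"k\" value=\"5\"/></listOfParameters>\n",
    "<listOfReactions>\n",
    "<reaction id=\"R1\" reversible=\"false\">\n",
    "<listOfReactants><speciesReference species=\"A\"/></listOfReactants>\n",
    "<listOfProducts><speciesReference species=\"B\"/></listOfProducts>\n",
    law(), "\n</reaction>\n",
    "<reaction id=\"R2\" reversible=\"false\">\n",
    "<listOfReactants><speciesReference species=\"B\"/></listOfReactants>\n",
    "<listOfProducts><speciesReference species=\"A\"/></listOfProducts>\n",
    law(), "\n</reaction>\n",
    "</listOfReactions>\n"
  ))
}

# species C defined by an assignment rule C := A + B; its value feeds R1
doc_assignment_species <- function() {
  sbml_wrap(paste0(
    "<listOfCompartments><compartment id=\"c\" size=\"1\"/></listOfCompartments>\n",
    "<listOfSpecies>\n",
    "<species id=\"A\" compartment=\"c\" initialConcentration=\"1\"/>\n",
    "<species id=\"B\" compartment=\"c\" initialConcentration=\"2\"/>\n",
    "<species id=\"C\" compartment=\"c\"/>\n",
    "</listOfSpecies>\n",
    "<listOfParameters><parameter id=\"k1\" value=\"0.5\"/></listOfParameters>\n",
    "<listOfRules><assignmentRule variable=\"C\">",
    math("<apply><plus/><ci>A</ci><ci>B</ci></apply>"),
    "</assignmentRule></listOfRules>\n",
    "<listOfReactions>\n",
    "<reaction id=\"R1\" reversible=\"false\">\n",
    "<listOfReactants><speciesReference species=\"A\"/></listOfReactants>\n",
    "<listOfProducts><speciesReference species=\"B\"/></listOfProducts>\n",
    "<kineticLaw>", math("<apply><times/><ci>k1</ci><ci>C</ci></apply>"), "</kineticLaw>\n",
    "</reaction>\n</listOfReactions>\n"
  ))
}

# species C governed by the rate rule dC/dt = k2 * t  (non-autonomous)
doc_rate_rule_time <- function() {
  d <- doc_minimal()
  d <- sub("</listOfSpecies>",
           "<species id=\"C\" compartment=\"c\" initialConcentration=\"0\"/></listOfSpecies>",
           d, fixed = TRUE)
  d <- sub("</listOfParameters>",
           "<parameter id=\"k2\" value=\"3\"/></listOfParameters>", d, fixed = TRUE)
  sub("<listOfReactions>", paste0(
    "<listOfRules><rateRule variable=\"C\">",
    math(paste0(
      "<apply><times/><ci>k2</ci>",
      "<csymbol encoding=\"text\" definitionURL=\"http://www.sbml.org/sbml/symbols/time\">t</csymbol>",
      "</apply>"
    )),
    "</rateRule></listOfRules>\n<listOfReactions>"
  ), d, fixed = TRUE)
}

# compartment of size 2, species initialised by amount
doc_compartment2 <- function() {
  d <- doc_minimal()
  d <- sub("size=\"1\"", "size=\"2\"", d, fixed = TRUE)
  sub("<species id=\"A\" compartment=\"c\" initialConcentration=\"1\"/>",
      "<species id=\"A\" compartment=\"c\" initialAmount=\"4\"/>", d, fixed = TRUE)
}

read_math_ex <- function(inner) {
  sbml2ode:::mathml_to_ex(xml2::read_xml(math(inner)))
}

# independent rank oracle: fraction-free elimination on an integer matrix,
# written separately from the package's exact path
helper_int_rank <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A); r <- ncol(A)
  if (n == 0 || r == 0) return(0L)
  prev <- 1; rank <- 0L; cc <- 1L
  while (cc <= r && rank < n) {
    piv <- which(A[(rank + 1):n, cc] != 0)
    if (!length(piv)) { cc <- cc + 1L; next }
    piv <- piv[1] + rank
    if (piv != rank + 1) A[c(piv, rank + 1), ] <- A[c(rank + 1, piv), ]
    p <- A[rank + 1, cc]
    if (rank + 2 <= n) {
      for (i in (rank + 2):n) A[i, ] <- (p * A[i, ] - A[i, cc] * A[rank + 1, ]) / prev
    }
    prev <- p; rank <- rank + 1L; cc <- cc + 1L
  }
  rank
}

rq_chr <- function(q) format(q)

# TRUE when a floating literal appears outside comment lines of a CAS export
has_float_literal <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  any(grepl("[0-9]\\.[0-9]", lines[!grepl("^\\s*[#%]", lines)]))
}
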