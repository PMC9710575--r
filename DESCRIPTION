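Package: sbml2ode
Title: Exact Symbolic ODE Systems from SBML Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts SBML (Systems Biology Markup Language) reaction-network
    models into exact symbolic ordinary differential equation systems suitable
    for computer algebra. All numeric literals become exact rational numbers;
    stoichiometric and kinetic matrices, linear conservation laws (primitive
    integer left-kernel bases), chemical reaction network theory deficiency,
    and a polynomial/rational/mass-action classification of the vector field
    are computed exactly. Species and parameters are canonically renamed to
    x1..xn and k1..km with a bijective name map, and datasets can be exported
    in Maple, Reduce, SageMath and LaTeX dialects plus a JSON manifest. A
    seeded fixture generator produces SBML documents with known ground truth
    for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
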