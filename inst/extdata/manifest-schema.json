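{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sbml2ode dataset manifest",
  "description": "Machine-readable companion written next to every dialect export. All numeric values that describe the model (matrix entries, parameter values, totals) are exact rational strings of the form 'p/q' or 'p'; they are never JSON floats.",
  "type": "object",
  "required": [
    "tool", "tool_version", "source", "species", "parameters", "reactions",
    "variables", "equations", "parameter_values", "initial_values",
    "constraints", "conservation_laws", "stoichiometric_matrix",
    "kinetic_matrix", "deficiency", "classification", "autonomous"
  ],
  "properties": {
    "tool": { "type": "string" },
    "tool_version": { "type": "string" },
    "source": { "type": "string" },
    "model_id": { "type": ["string", "null"] },
    "divide_by_compartment": { "type": "boolean" },
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "boundary", "assignment_rule", "rate_rule"],
        "properties": {
          "id": { "type": "string" },
          "name": { "type": "string", "pattern": "^x[0-9]+$" },
          "boundary": { "type": "boolean" },
          "assignment_rule": { "type": "boolean" },
          "rate_rule": { "type": "boolean" },
          "compartment": { "type": ["string", "null"] }
        }
      }
    },
    "parameters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "origin"],
        "properties": {
          "id": { "type": "string" },
          "name": { "type": "string", "pattern": "^k[0-9]+$" },
          "value": { "type": ["string", "null"], "pattern": "^-?[0-9]+(/[0-9]+)?$" },
          "origin": { "type": "string" }
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "reversible", "mass_action"],
        "properties": {
          "id": { "type": "string" },
          "reversible": { "type": "boolean" },
          "mass_action": { "type": "boolean" }
        }
      }
    },
    "variables": { "type": "array", "items": { "type": "string" } },
    "equations": {
      "type": "object",
      "additionalProperties": { "type": "string" }
    },
    "parameter_values": {
      "type": "object",
      "additionalProperties": { "type": "string", "pattern": "^-?[0-9]+(/[0-9]+)?$" }
    },
    "initial_values": {
      "type": "object",
      "additionalProperties": { "type": "string", "pattern": "^-?[0-9]+(/[0-9]+)?$" }
    },
    "constraints": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["kind", "lhs", "rhs"],
        "properties": {
          "kind": { "enum": ["species-assignment", "conservation"] },
          "lhs": { "type": "string" },
          "rhs": { "type": "string" }
        }
      }
    },
    "conservation_laws": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["coefficients", "variables"],
        "properties": {
          "coefficients": { "type": "array", "items": { "type": "integer" } },
          "variables": { "type": "array", "items": { "type": "string" } },
          "total": { "type": ["string", "null"], "pattern": "^-?[0-9]+(/[0-9]+)?$" }
        }
      }
    },
    "stoichiometric_matrix": {
      "type": "array",
      "items": { "type": "array", "items": { "type": "string", "pattern": "^-?[0-9]+(/[0-9]+)?$" } }
    },
    "kinetic_matrix": {
      "type": "array",
      "items": { "type": "array", "items": { "type": "string", "pattern": "^-?[0-9]+(/[0-9]+)?$" } }
    },
    "deficiency": {
      "type": "object",
      "required": ["n_complexes", "n_linkage_classes", "rank", "deficiency"],
      "properties": {
        "n_complexes": { "type": "integer", "minimum": 0 },
        "n_linkage_classes": { "type": "integer", "minimum": 0 },
        "rank": { "type": "integer", "minimum": 0 },
        "deficiency": { "type": "integer", "minimum": 0 }
      }
    },
    "classification": {
      "type": "object",
      "required": ["vector_field_class", "constraints_class", "mass_action"],
      "properties": {
        "vector_field_class": { "enum": ["polynomial", "rational", "other"] },
        "constraints_class": { "enum": ["polynomial", "rational", "other"] },
        "mass_action": { "type": "boolean" }
      }
    },
    "autonomous": { "type": "boolean" }
  }
}
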