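{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "ceatree-model/1.0",
  "title": "ceatree model configuration",
  "description": "Decision-tree cost-utility model: parameter table, one decision root over strategies with chance/terminal nodes, and analysis settings. Payoff and probability expressions are strings over parameter names, numeric literals, + - * / and parentheses; a chance branch probability may be the keyword 'complement' (at most one per chance node), resolved as one minus the sum of its siblings.",
  "type": "object",
  "required": ["parameters", "tree", "settings"],
  "properties": {
    "schema": { "const": "ceatree-model/1.0" },
    "parameters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "kind", "base"],
        "properties": {
          "name": { "type": "string", "minLength": 1 },
          "kind": { "enum": ["probability", "utility", "cost", "rate", "count"] },
          "base": { "type": "number" },
          "low": { "type": "number" },
          "high": { "type": "number" },
          "dist": {
            "type": "object",
            "required": ["family"],
            "properties": {
              "family": { "enum": ["beta", "gamma", "uniform", "fixed"] },
              "mean": { "type": "number" },
              "se": { "type": "number", "minimum": 0 }
            }
          }
        }
      }
    },
    "tree": {
      "type": "object",
      "required": ["strategies"],
      "properties": {
        "label": { "type": "string" },
        "strategies": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/node" }
        }
      }
    },
    "settings": {
      "type": "object",
      "required": ["wtp"],
      "properties": {
        "wtp": { "type": "number", "minimum": 0 },
        "discount_rate": { "type": "number", "exclusiveMinimum": -1 },
        "horizon_months": { "type": "number", "exclusiveMinimum": 0 },
        "effectiveness_mode": { "enum": ["utility_at_horizon", "time_integrated"] },
        "psa_draws": { "type": "integer", "minimum": 1 },
        "seed": { "type": "integer" }
      }
    }
  },
  "definitions": {
    "node": {
      "type": "object",
      "required": ["kind"],
      "properties": {
        "kind": { "enum": ["chance", "terminal"] },
        "label": { "type": "string" },
        "cost": { "type": "string" },
        "effect": { "type": "string" },
        "branches": {
          "type": "array",
          "minItems": 1,
          "items": {
            "type": "object",
            "required": ["prob", "node"],
            "properties": {
              "prob": { "type": "string" },
              "node": { "$ref": "#/definitions/node" }
            }
          }
        }
      }
    }
  }
}
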