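{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Exergame game description",
  "description": "YAML/JSON document mirroring the GameDescription fields; loadable with exergraph::game_from_yaml().",
  "type": "object",
  "required": ["iri", "label", "metrics"],
  "properties": {
    "iri": { "type": "string", "format": "iri" },
    "label": { "type": "string", "minLength": 1 },
    "metrics": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["label"],
        "properties": {
          "local_name": { "type": "string", "description": "Fragment in http://purl.org/net/exergame/metric#; alternative to iri." },
          "iri": { "type": "string", "format": "iri" },
          "label": { "type": "string", "minLength": 1 },
          "concept": { "type": "string", "format": "iri" },
          "unit": { "type": "string", "format": "iri" }
        },
        "anyOf": [ { "required": ["local_name"] }, { "required": ["iri"] } ]
      }
    },
    "controllers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label"],
        "properties": {
          "local_name": { "type": "string" },
          "iri": { "type": "string", "format": "iri" },
          "label": { "type": "string" },
          "same_as": { "type": "string", "format": "iri", "description": "DBpedia resource linked with owl:sameAs." }
        },
        "anyOf": [ { "required": ["local_name"] }, { "required": ["iri"] } ]
      }
    },
    "presentation_hardware": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["iri", "label"],
        "properties": {
          "iri": { "type": "string", "format": "iri" },
          "label": { "type": "string" }
        }
      }
    },
    "exercise": {
      "type": "object",
      "required": ["iri", "label"],
      "properties": {
        "iri": { "type": "string", "format": "iri" },
        "label": { "type": "string" },
        "muscles": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["iri", "source"],
            "properties": {
              "iri": { "type": "string", "format": "iri" },
              "source": { "enum": ["OPE", "NCIt-subclass"] }
            }
          }
        },
        "equipment": { "type": "array", "items": { "type": "string" } },
        "benefits": { "type": "array", "items": { "type": "string" } }
      }
    },
    "goals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["kind", "text"],
        "properties": {
          "kind": { "enum": ["game_goal", "exercise_goal"] },
          "text": { "type": "string", "minLength": 1 }
        }
      }
    }
  }
}
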