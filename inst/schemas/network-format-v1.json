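{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "network-format-v1.json",
  "title": "metnav native network format, version 1",
  "type": "object",
  "required": ["format", "version", "id", "metabolites", "reactions"],
  "properties": {
    "format": { "const": "metnav-network" },
    "version": { "const": 1 },
    "id": { "type": "string", "minLength": 1 },
    "ubiquitous": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Metabolite ids omitted from precursor/successor lists; must be a subset of metabolite ids."
    },
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "name": { "type": "string" },
          "smiles": { "type": "string" },
          "is_ubiquitous": { "type": "boolean" }
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "left", "right", "direction"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "left": { "$ref": "#/definitions/side" },
          "right": { "$ref": "#/definitions/side" },
          "direction": {
            "enum": ["LEFT_TO_RIGHT", "RIGHT_TO_LEFT", "REVERSIBLE", "UNSPECIFIED"]
          },
          "equation": { "type": "string" },
          "ec_number": { "type": "string" },
          "enzymes": { "type": "array", "items": { "type": "string" } },
          "genes": { "type": "array", "items": { "type": "string" } },
          "pathways": { "type": "array", "items": { "type": "string" } },
          "spontaneous": { "type": "boolean" }
        }
      }
    }
  },
  "definitions": {
    "side": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["metabolite"],
        "properties": {
          "metabolite": { "type": "string", "minLength": 1 },
          "coefficient": { "type": "number", "exclusiveMinimum": 0 }
        }
      }
    }
  }
}
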