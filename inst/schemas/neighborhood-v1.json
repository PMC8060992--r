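{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "neighborhood-v1.json",
  "title": "metnav neighbors command JSON output, version 1",
  "type": "object",
  "required": ["format", "version", "network", "focal", "precursors", "successors"],
  "properties": {
    "format": { "const": "metnav-neighborhood" },
    "version": { "const": 1 },
    "network": { "type": "string" },
    "focal": { "type": "string" },
    "precursors": { "$ref": "#/definitions/entries" },
    "successors": { "$ref": "#/definitions/entries" }
  },
  "definitions": {
    "entries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["neighbor", "name", "reactions", "class"],
        "properties": {
          "neighbor": { "type": "string" },
          "name": { "type": "string" },
          "reactions": {
            "type": "array", "minItems": 1, "items": { "type": "string" }
          },
          "class": {
            "enum": ["UNIDIRECTIONAL", "BIDIRECTIONAL", "SPONTANEOUS", "MULTIPLE"]
          }
        }
      }
    }
  }
}
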