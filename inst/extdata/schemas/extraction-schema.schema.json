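{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/taxograph/extraction-schema.schema.json",
  "title": "Extraction schema for XML-to-RDF conversion",
  "type": "object",
  "required": ["dialect", "root", "nodes", "coverage"],
  "properties": {
    "dialect": { "enum": ["TaxPub", "TaxonX"] },
    "description": { "type": "string" },
    "xmlns": {
      "type": "object",
      "additionalProperties": { "type": "string", "format": "uri" }
    },
    "root": { "type": "string" },
    "coverage": {
      "type": "object",
      "additionalProperties": { "type": "boolean" }
    },
    "nodes": {
      "type": "object",
      "additionalProperties": { "$ref": "#/definitions/node" }
    }
  },
  "definitions": {
    "node": {
      "type": "object",
      "required": ["resource_type", "location", "constructor", "atoms", "children"],
      "properties": {
        "resource_type": { "type": "string", "pattern": "^[a-z][a-z_]*$" },
        "location": { "type": "string", "minLength": 1 },
        "constructor": { "type": "string" },
        "kind": { "type": "string" },
        "resolve_affiliations": { "type": "boolean" },
        "atoms": {
          "type": "object",
          "additionalProperties": { "$ref": "#/definitions/atom" }
        },
        "children": {
          "type": "array",
          "items": { "type": "string" }
        }
      }
    },
    "atom": {
      "type": "object",
      "required": ["location", "value_kind", "semantic_kind"],
      "properties": {
        "location": { "type": "string", "minLength": 1 },
        "value_kind": { "enum": ["element-text", "attribute"] },
        "semantic_kind": { "enum": ["string", "link", "date", "integer", "identifier"] }
      }
    }
  }
}
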