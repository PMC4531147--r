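{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Component library (JSON dialect)",
  "type": "object",
  "required": ["components"],
  "properties": {
    "schema_version": { "type": "string" },
    "comment": { "type": "string" },
    "components": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "gubs"],
        "properties": {
          "name": {
            "type": "string",
            "minLength": 1,
            "description": "Unique component identifier"
          },
          "gubs": {
            "type": "string",
            "description": "Behaviour of the component as DSL source text"
          }
        }
      }
    }
  }
}
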