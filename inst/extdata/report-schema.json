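{
  "title": "radelim pipeline report",
  "type": "object",
  "required": ["seed", "stages", "sections"],
  "properties": {
    "seed": {"type": "integer"},
    "stages": {"type": "array"},
    "sections": {
      "type": "object",
      "sectionStatus": ["present", "absent"]
    }
  }
}
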