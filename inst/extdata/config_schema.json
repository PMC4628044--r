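{
  "title": "triqsar pipeline configuration",
  "type": "object",
  "properties": {
    "structures": {
      "type": "object",
      "properties": {
        "path": {"type": "string", "description": "structure file (SDF/XYZ/SMILES)"},
        "format": {"enum": ["auto", "sdf", "xyz", "smiles"]}
      }
    },
    "activities": {
      "type": "object",
      "properties": {"path": {"type": "string", "description": "activity table: compound_id, cell_line, ic50_uM, inactive"}}
    },
    "descriptors": {
      "type": "object",
      "properties": {
        "path": {"type": "string", "description": "precomputed descriptor table"},
        "beta": {"type": "number", "description": "RDF smoothing, 1/Angstrom^2", "default": 100},
        "include_hydrogens": {"type": "boolean", "default": true},
        "weight_table": {"type": "string", "description": "override element property table"}
      }
    },
    "selection": {
      "type": "object",
      "properties": {
        "cor_threshold": {"type": "number", "default": 0.6, "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "p_enter": {"type": "number", "default": 0.05},
        "p_remove": {"type": "number", "default": 0.10}
      }
    },
    "cell_lines": {"type": "array", "items": {"enum": ["HuCCA-1", "HepG2", "A549", "MOLT-3"]}},
    "seed": {"type": "integer", "default": 1},
    "out_dir": {"type": "string", "default": "."}
  }
}
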