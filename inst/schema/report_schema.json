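{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "swnsyn reproduction report",
  "type": "object",
  "required": ["tool", "version", "seed", "presence", "characters", "parsimony"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "presence": {
      "type": "object",
      "required": ["n_taxa", "gene_frequency", "n_orders_excluding_plant"]
    },
    "characters": {
      "type": "object",
      "required": ["n_taxa", "n_characters", "type_counts", "character_counts"]
    },
    "parsimony": {
      "type": "object",
      "required": ["score", "n_trees", "method", "n_unique_changes"]
    }
  }
}
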