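{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "VariantRecord",
  "description": "Integrated annotation for one human genomic variant as exchanged between the variant store and the prompt assembler. The field roster mirrors the summarized attributes of the public variant-database API response; the concrete layout is defined by this artifact.",
  "type": "object",
  "required": ["togovar_id", "chromosome", "position", "ref", "alt"],
  "additionalProperties": false,
  "properties": {
    "togovar_id": {"type": "string", "minLength": 1},
    "rs_id": {"type": "string", "pattern": "^rs[0-9]+$"},
    "chromosome": {
      "type": "string",
      "enum": ["1","2","3","4","5","6","7","8","9","10","11","12","13","14","15","16","17","18","19","20","21","22","X","Y","MT"]
    },
    "position": {"type": "integer", "minimum": 1,
                 "description": "1-based position on GRCh38"},
    "ref": {"type": "string", "pattern": "^[ACGT]+$"},
    "alt": {"type": "string", "pattern": "^[ACGT]+$"},
    "gene_symbol": {"type": "string"},
    "clinical_significance": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["condition"],
        "properties": {
          "condition": {"type": "string"},
          "interpretations": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "most_severe_consequence": {
      "type": "object",
      "required": ["accession", "label"],
      "properties": {
        "accession": {"type": "string", "pattern": "^SO_[0-9]+$"},
        "label": {"type": "string"}
      }
    },
    "hgvs": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "protein": {"type": "string"},
        "cdna": {"type": "string"},
        "genomic": {"type": "string"}
      }
    },
    "predictions": {
      "type": "object",
      "description": "tool name -> score and qualitative label; SIFT, PolyPhen and AlphaMissense scores lie in [0, 1]",
      "additionalProperties": {
        "type": "object",
        "required": ["score", "label"],
        "properties": {
          "score": {"type": "number"},
          "label": {"type": "string"}
        }
      }
    },
    "allele_frequencies": {
      "type": "object",
      "description": "population dataset name (free-form) -> alternate allele frequency",
      "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "external_links": {
      "type": "object",
      "additionalProperties": {"type": "string", "format": "uri"}
    }
  }
}
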