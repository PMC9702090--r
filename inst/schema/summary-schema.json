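{
  "title": "envmet pipeline summary",
  "type": "object",
  "required": [
    "seed", "k", "environments", "me_assignment",
    "w_columns_before_qc", "w_columns_after_qc", "kernel_trace",
    "traits", "heritability", "selected", "fa_explained", "config"
  ]
}
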