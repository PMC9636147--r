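{
  "required": ["diversity", "haplogroup_composition", "founder_lineages", "founder_fractions", "ages", "amova", "amova_no_founders", "composition_chi2", "pathogenicity", "provenance"]
}
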