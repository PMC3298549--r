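# Example provenance pattern: a gene-knockout entry form capturing the
# responsible researcher and the experiment priority.
elements:
  - class: gene_knockout_process
  - class: researcher
    property: has_agent
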