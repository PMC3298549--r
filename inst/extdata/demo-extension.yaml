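# Example schema-extension config: a sonication-specific transfection
# process with a dedicated participant property.
classes:
  - name: sonication_transfection_process
    parent: transfection_process
properties:
  - name: sonicates
    domain: sonication_transfection_process
    range: data_collection
    parent: has_participant
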