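journal	group
Journal of broad science 1	broad
Journal of broad science 2	broad
Journal of broad science 3	broad
Journal of field science 1	field
Journal of field science 2	field
Journal of field science 3	field
Journal of specialist science 1	specialist
Journal of specialist science 2	specialist
Journal of specialist science 3	specialist
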