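MAGE-TAB Version	1.1
Investigation Title	Reconstructing the human first trimester fetal maternal interface
Experiment Description	Droplet based scRNA-seq of decidual and placental cells
SDRF File	E-MTAB-990001.sdrf.txt
Comment[AEExperimentType]	RNA-seq of coding RNA from single cells
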