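original_label,consolidated_label
Unconsolidated Substrate (Sand),1_UnCon Sub
Macroalgae,2_MA
Seagrass,3_SG
Sponge,ReefStructure
Hard Coral,ReefStructure
Soft Coral,ReefStructure
Consolidated Substrate,ReefStructure
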