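# connected reaction network 1
digraph {
 100233 [label = SBML_REACTION];
 100186 [label = SBML_SPECIES];
 100233 -> 100186 [label = HAS_PRODUCT];
 100229 [label = SBML_REACTION];
 100186 -> 100229 [label = IS_REACTANT];
}
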