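digraph "560" {
 Node_0 [label="SBML_REACTION"];
 Node_1 [label="SBML_SPECIES"];
 Node_2 [label="SBML_REACTION"];
 Node_3 [label="SBML_REACTION"];
 Node_4 [label="SBML_SPECIES"];
 Node_0 -> Node_1 [label="HAS_PRODUCT"];
 Node_1 -> Node_2 [label="IS_REACTANT"];
 Node_1 -> Node_3 [label="IS_REACTANT"];
 Node_4 -> Node_0 [label="IS_REACTANT"];
}#=> 398[, BIOMD0000000001, BIOMD0000000002,]

digraph "560" {
 Node_0 [label="SBML_REACTION"];
 Node_1 [label="SBML_SPECIES"];
 Node_0 -> Node_1 [label="HAS_PRODUCT"];
}#=> 436[, BIOMD0000000001,]
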