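# Published residue lists for vascular endothelial growth factor (1BJ1,
# chain W) under the rhuMAb mimotope set: the crystallographic epitope, the
# MimoPro candidate-epitope prediction, and the residues removed by the
# surface-pruning step.
epitope: I80 M81 R82 I83 K84 H86 Q87 G88 Q89 H90 I91 G92 E93 M94 F17 Y21 Y45 K48 Q79
predicted: V33 D34 F36 Q37 E38 Y39 P40 D41 E42 I43 E44 Y45 I46 F47 K48 P49 S50 C51 M78 M81 R82 I83 K84 P85 Q87 G88 Q89 H90 G92 E93 M94 S95
removed: 20V 27H 28P 40P 42E 47F 56R 58G 67E 68C 71T 78M 82R 98Q 100N
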