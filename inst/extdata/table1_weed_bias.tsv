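chromosome	BHA_like	SH_like
chr1	0.652	0.682
chr2	0.796	0.658
chr3	0.793	0.658
chr4	0.775	0.696
chr5	0.773	0.733
chr6	0.609	0.77
chr7	0.796	0.652
chr8	0.704	0.737
chr9	0.767	0.545
chr10	0.766	0.791
chr11	0.649	0.656
chr12	0.81	0.728
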