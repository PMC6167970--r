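material,group,character,min,max
type,robusta,lateral_line_scales,89,92
type,nigra,lateral_line_scales,73,93
type,intermedia,lateral_line_scales,59,71
type,robusta,body_depth,5.2,5.4
type,nigra,body_depth,4.1,4.6
type,intermedia,body_depth,3.7,4.0
type,robusta,head_length,3.5,3.6
type,nigra,head_length,3.5,3.6
type,intermedia,head_length,3.1,3.4
type,robusta,scales_above_lateral_line,21,23
type,nigra,scales_above_lateral_line,18,23
type,intermedia,scales_above_lateral_line,16,18
fresh,robusta,lateral_line_scales,82,95
fresh,nigra,lateral_line_scales,82,89
fresh,intermedia,lateral_line_scales,65,87
fresh,robusta,body_depth,3.9,5.3
fresh,nigra,body_depth,3.7,5.0
fresh,intermedia,body_depth,3.9,4.8
fresh,robusta,head_length,3.4,3.9
fresh,nigra,head_length,3.3,3.8
fresh,intermedia,head_length,3.5,3.8
fresh,robusta,scales_above_lateral_line,23,26
fresh,nigra,scales_above_lateral_line,20,23
fresh,intermedia,scales_above_lateral_line,17,21
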