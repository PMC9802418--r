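parameter,class,points
villous_number,normal,0
villous_number,edematous,1
villous_extent,none,0
villous_extent,short_segment,8
villous_extent,long_segment,12
villous_extent,whole_tertile,20
villous_descriptor,none,0
villous_descriptor,single,1
villous_descriptor,patchy,14
villous_descriptor,diffuse,17
ulcer_number,none,0
ulcer_number,single,3
ulcer_number,few,5
ulcer_number,multiple,10
ulcer_extent,none,0
ulcer_extent,short_segment,5
ulcer_extent,long_segment,10
ulcer_extent,whole_tertile,15
ulcer_size,none,0
ulcer_size,lt_quarter,9
ulcer_size,quarter_to_half,12
ulcer_size,gt_half,18
stenosis_number,none,0
stenosis_number,single,14
stenosis_number,multiple,20
stenosis_ulcerated,none,0
stenosis_ulcerated,nonulcerated,2
stenosis_ulcerated,ulcerated,24
stenosis_traversed,none,0
stenosis_traversed,traversed,7
stenosis_traversed,not_traversed,10
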