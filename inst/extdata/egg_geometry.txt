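# Classification geometry for the gastrointestinal-absorption /
# brain-access plot in the (TPSA, WLOGP) plane.
# Ellipses: centre (cx = TPSA, cy = WLOGP), full width/height along the
# rotated axes, rotation angle in degrees (counter-clockwise).
# white = high probability of passive gastrointestinal absorption (HIA)
# yolk  = high probability of blood-brain-barrier permeation (BBB)
white.cx     71.051
white.cy     2.292
white.width  142.081
white.height 8.740
white.angle  -1.031325
yolk.cx      38.117
yolk.cy      3.481
yolk.width   82.061
yolk.height  5.557
yolk.angle   -0.14957
# plot range; points outside are reported out-of-range (neither HIA nor BBB)
range.tpsa_min   0
range.tpsa_max   200
range.wlogp_min  -4
range.wlogp_max  8
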