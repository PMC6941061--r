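# Example run configuration: the adjusted preset with a reduced capillary
# hemodynamic factor (residence time x4) and a mildly lowered perfusion.
preset = "rcmstar"
RBF = 4.0
capFactor = 0.25
PTC_feed = 56
LUM_feed = 40
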