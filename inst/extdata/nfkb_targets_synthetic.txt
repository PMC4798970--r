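# Synthetic NF-kB target gene list for the default expression panel.
# Stand-in for curated target lists (one gene id per line).
oscillating_01
oscillating_02
oscillating_03
oscillating_04
oscillating_05
oscillating_06
oscillating_07
oscillating_08
oscillating_09
oscillating_10
oscillating_11
oscillating_12
oscillating_13
oscillating_14
oscillating_15
oscillating_16
oscillating_17
oscillating_18
oscillating_19
oscillating_20
fast_up_01
fast_up_02
fast_up_03
fast_up_04
fast_up_05
fast_up_06
fast_up_07
fast_up_08
fast_up_09
fast_up_10
fast_up_11
fast_up_12
fast_up_13
fast_up_14
fast_up_15
fast_up_16
fast_up_17
fast_up_18
fast_up_19
fast_up_20
slow_up_01
slow_up_02
slow_up_03
slow_up_04
slow_up_05
slow_up_06
slow_up_07
slow_up_08
slow_up_09
slow_up_10
slow_up_11
slow_up_12
slow_up_13
slow_up_14
slow_up_15
slow_up_16
slow_up_17
slow_up_18
slow_up_19
slow_up_20
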