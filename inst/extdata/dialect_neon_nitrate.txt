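# NEON-style 15-minute nitrate layout
timestamp = startDateTime
value = surfWaterNitrateMean
flag = finalQF
variable = nitrate
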