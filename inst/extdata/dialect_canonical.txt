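# canonical sensor-table layout
timestamp = timestamp
value = value
flag = qc_flag
variable = nitrate
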