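startDateTime,surfWaterNitrateMean,finalQF
2019-03-01T00:00:00Z,27.693,0
2019-03-01T00:15:00Z,27.367,0
2019-03-01T00:30:00Z,27.31,0
2019-03-01T00:45:00Z,27.199,0
2019-03-01T01:00:00Z,27.374,0
2019-03-01T01:15:00Z,26.899,0
2019-03-01T01:30:00Z,27.376,0
2019-03-01T01:45:00Z,27.368,0
2019-03-01T02:00:00Z,27.269,0
2019-03-01T02:15:00Z,27.124,0
2019-03-01T02:30:00Z,27.635,0
2019-03-01T02:45:00Z,27.447,0
2019-03-01T03:00:00Z,27.476,0
2019-03-01T03:15:00Z,27.369,0
2019-03-01T03:30:00Z,28.108,0
2019-03-01T03:45:00Z,27.772,0
2019-03-01T04:00:00Z,27.741,0
2019-03-01T04:15:00Z,26.694,0
2019-03-01T04:30:00Z,27.049,0
2019-03-01T04:45:00Z,26.766,0
2019-03-01T05:00:00Z,27.469,1
2019-03-01T05:15:00Z,27.542,0
2019-03-01T05:30:00Z,27.435,0
2019-03-01T05:45:00Z,27.805,0
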