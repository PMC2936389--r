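1	"Outcome and Process Assessment (Health Care)" [mh]
2	"Hospital Units" [mh]
3	hospitals[tiab]
4	#1 OR #2 OR #3
5	nurse[tiab] or nurses[tiab]
6	staffing[tiab]
7	"Nursing Staff, Hospital" [mh]
8	#6 OR #7
9	outcomes[tiab]
10	#4 AND #5 AND #8 AND #9
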