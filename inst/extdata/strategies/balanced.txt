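1	"Outcome and Process Assessment (Health Care)" [mh]
2	"Hospital Units" [mh]
3	hospitals[tiab]
4	#1 OR #2 OR #3
5	(nurse[tiab] OR nurses[tiab]) AND staffing[tiab]
6	"Nursing Staff, Hospital" [mh]
7	#5 OR #6
8	#4 AND #7
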