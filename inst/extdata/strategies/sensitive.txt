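1	staff[tiab] OR staffing[tiab] OR organizational[tiab] OR skill mix[tiab] OR length of stay[tiab] OR medicare[tiab]
2	"Nursing Staff, Hospital"[mh]
3	"Personnel Staffing and Scheduling"[mh]
4	"Intensive Care Units/manpower"[mh]
5	"Nursing Administration Research"[mh]
6	#1 OR #2 OR #3 OR #4 OR #5
7	"health services administration"[mh]
8	nurse[tiab] OR nurses[tiab] OR hospitals[tiab] OR nursing[tiab]
9	"hospital units"[mh]
10	#8 OR #9
11	#6 AND #7 AND #10
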