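# Published median creatinine-adjusted concentrations (ug/g) by sampling window
# for the firefighting-instructor live-fire-training cohort (n per window 22-30)
window_index,analyte,median
1,DHN,2.23
1,NAP1,0.61
1,NAP2,2.00
1,PYR1,0.06
2,DHN,3.32
2,NAP1,0.39
2,NAP2,1.94
2,PYR1,0.05
3,DHN,31.60
3,NAP1,4.34
3,NAP2,7.42
3,PYR1,0.06
4,DHN,134.15
4,NAP1,12.08
4,NAP2,11.96
4,PYR1,0.20
5,DHN,131.46
5,NAP1,10.79
5,NAP2,10.07
5,PYR1,0.40
6,DHN,86.01
6,NAP1,4.53
6,NAP2,5.12
6,PYR1,0.29
7,DHN,51.58
7,NAP1,3.33
7,NAP2,3.48
7,PYR1,0.25
8,DHN,46.02
8,NAP1,2.86
8,NAP2,3.14
8,PYR1,0.21
9,DHN,27.08
9,NAP1,2.66
9,NAP2,3.26
9,PYR1,0.17
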