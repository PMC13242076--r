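arm,timepoint,domain,n,neither,clinician_only,patient_only,both,kappa
A,mid,diarrhea,666,495,27,95,49,0.35
A,mid,nausea,667,149,76,155,287,0.29
A,mid,vomiting,671,522,55,64,30,0.23
A,mid,mucositis,664,95,37,265,267,0.13
A,mid,fatigue,653,38,73,129,413,0.09
A,mid,pain,658,310,95,145,108,0.20
B,mid,diarrhea,705,504,46,114,41,0.21
B,mid,nausea,705,206,182,98,219,0.22
B,mid,vomiting,709,573,69,41,26,0.24
B,mid,mucositis,704,150,54,303,197,0.09
B,mid,fatigue,698,104,116,165,313,0.12
B,mid,pain,697,365,108,153,71,0.09
A,end,diarrhea,587,326,26,147,88,0.33
A,end,nausea,590,378,37,121,54,0.25
A,end,vomiting,589,551,8,23,7,0.29
A,end,mucositis,586,49,23,289,225,0.05
A,end,fatigue,583,26,42,130,385,0.08
A,end,pain,581,131,73,152,225,0.22
B,end,diarrhea,696,421,48,149,78,0.27
B,end,nausea,698,487,39,115,57,0.30
B,end,vomiting,699,649,12,30,8,0.25
B,end,mucositis,688,106,64,300,218,0.03
B,end,fatigue,689,61,69,151,408,0.16
B,end,pain,687,165,178,135,209,0.09
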