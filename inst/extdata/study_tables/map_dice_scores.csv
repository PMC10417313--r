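case,condition,method,N,T,R
C32,control,NMF,0.88,0.90,NA
C69,control,NMF,0.84,0.72,NA
C71,control,NMF,0.67,0.71,NA
C179,control,NMF,0.73,0.55,NA
C233,control,NMF,0.89,0.91,NA
C234,control,NMF,0.91,0.94,NA
C278,control,NMF,0.90,0.87,NA
C255,control,NMF,0.85,0.80,NA
C288,control,NMF,0.82,0.72,NA
C351,control,NMF,0.86,0.55,NA
C520,control,NMF,0.68,0.90,NA
C529,control,NMF,0.69,0.74,NA
C583,control,NMF,0.86,0.93,NA
C437,treated,NMF,0.76,NA,0.95
C525,treated,NMF,0.90,NA,0.00
C527,treated,NMF,0.94,NA,0.79
C575,treated,NMF,0.96,NA,0.12
C584,treated,NMF,0.94,NA,0.69
C586,treated,NMF,0.85,NA,0.95
C32,control,CNN,0.91,0.93,NA
C69,control,CNN,0.95,0.91,NA
C71,control,CNN,0.77,0.86,NA
C179,control,CNN,0.86,0.89,NA
C233,control,CNN,0.92,0.94,NA
C234,control,CNN,0.89,0.94,NA
C278,control,CNN,0.70,0.86,NA
C255,control,CNN,0.86,0.88,NA
C288,control,CNN,0.93,0.86,NA
C351,control,CNN,0.86,0.87,NA
C520,control,CNN,0.60,0.88,NA
C529,control,CNN,0.86,0.96,NA
C583,control,CNN,0.94,0.96,NA
C437,treated,CNN,0.96,NA,0.92
C525,treated,CNN,1.00,NA,0.87
C527,treated,CNN,0.95,NA,0.96
C575,treated,CNN,0.91,NA,0.91
C584,treated,CNN,0.95,NA,0.89
C586,treated,CNN,0.90,NA,0.99
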