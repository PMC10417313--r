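case,condition,design,test_set
C32,control,single,TRUE
C69,control,single,FALSE
C71,control,single,FALSE
C179,control,single,TRUE
C233,control,single,FALSE
C234,control,single,FALSE
C278,control,single,TRUE
C255,control,single,FALSE
C288,control,single,FALSE
C351,control,single,FALSE
C520,control,single,FALSE
C529,control,single,FALSE
C583,control,single,FALSE
C415,treated,single,FALSE
C418,treated,single,FALSE
C437,treated,single,TRUE
C525,treated,single,TRUE
C527,treated,single,FALSE
C575,treated,single,FALSE
C584,treated,single,TRUE
C586,treated,single,FALSE
C797,treated,longitudinal,FALSE
C806,treated,longitudinal,FALSE
C808,treated,longitudinal,FALSE
C809,treated,longitudinal,FALSE
C817,treated,longitudinal,TRUE
C819,treated,longitudinal,FALSE
C821,treated,longitudinal,FALSE
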