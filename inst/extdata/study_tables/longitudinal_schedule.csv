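case,day
C797,10
C797,15
C797,17
C797,18
C797,20
C797,22
C806,11
C806,12
C806,14
C806,16
C806,18
C806,20
C806,22
C806,24
C808,10
C808,12
C808,14
C808,16
C808,18
C808,20
C808,22
C808,24
C808,26
C808,28
C808,33
C809,11
C809,12
C809,14
C809,16
C809,18
C809,20
C809,22
C809,24
C809,26
C809,28
C809,31
C809,33
C817,10
C817,12
C817,14
C817,16
C817,18
C817,20
C817,22
C817,24
C817,26
C817,28
C817,30
C817,32
C817,35
C817,39
C817,45
C817,48
C817,50
C817,56
C817,58
C817,61
C817,63
C817,66
C817,68
C817,70
C819,10
C819,12
C819,14
C819,16
C819,18
C819,20
C819,22
C819,24
C819,26
C819,28
C819,30
C819,32
C819,34
C819,36
C819,39
C819,41
C819,43
C819,45
C821,10
C821,12
C821,14
C821,16
C821,18
C821,20
C821,22
C821,24
C821,26
C821,28
C821,30
C821,32
C821,34
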