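# Typical parameter values of the BGCT loop model (flat key-value file
# for read_params()/load_config()).  Keys omitted here keep the same
# defaults; the striatal output weights T42 / T53 are the usual free
# parameters.  Note: quote 'n' — a bare n is a YAML 1.1 boolean.
C1: 3.60
C2: 3.60
C3: 3.60
C4: 3.60
C5: 3.60
C6: 3.60
C7: 3.60
R1: 1.67
R2: 1.67
R3: 1.67
R4: 1.67
R5: 1.67
R6: 1.67
R7: 1.67
T16: 2
T21: 1.4
T26: 1.4
T31: 1.4
T36: 1.4
T42: 1
T45: 3
T47: 2
T53: 1
T57: 1
T64: 3.2
T71: 1.8
T75: 1.8
I1: 0.1
I2: 0.05
I3: 1.2
I4: 4.4
I5: 2.8
I6: 2
I7: 1.2
s: 2
'n': 2
Dinput: 0.6
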