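#name=synthetic30
#intercept=0.59999999999999998
#transform=log_linear
#adult_age=20
probe_id,coefficient
cg00000001,0.59999999999999998
cg00000002,-0.23999999999999999
cg00000003,0.21000000000000002
cg00000004,-0.17999999999999999
cg00000005,0.16
cg00000006,-0.13999999999999999
cg00000007,0.125
cg00000008,-0.11000000000000001
cg00000009,0.10000000000000001
cg00000010,-0.089999999999999997
cg00000011,0.080000000000000002
cg00000012,-0.071999999999999995
cg00000013,0.065000000000000002
cg00000014,-0.057999999999999996
cg00000015,0.052000000000000005
cg00000016,-0.047
cg00000017,0.041999999999999996
cg00000018,-0.037999999999999999
cg00000019,0.034000000000000002
cg00000020,-0.029999999999999999
cg00000021,0.027000000000000003
cg00000022,-0.024
cg00000023,0.020999999999999998
cg00000024,-0.019
cg00000025,0.017000000000000001
cg00000026,-0.014999999999999999
cg00000027,0.013000000000000001
cg00000028,-0.010999999999999999
cg00000029,0.01
cg00000030,-0.0080000000000000002
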