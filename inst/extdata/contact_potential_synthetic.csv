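# Synthetic pairwise amino-acid contact potential (lower = more favorable).
# Constructed stand-in calibrated to reproduce the published SLE/RA
# immunogenic-peptide preference orderings; NOT the Simons et al. values.
aa,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V
A,-0.165,0.285,0.242,0.191,-0.186,0.130,0.127,0.033,0.223,-0.214,-0.207,0.265,-0.144,-0.127,0.087,0.010,0.058,0.146,0.046,-0.180
R,0.285,-0.236,-0.468,-0.769,0.342,-0.423,-0.878,-0.082,-0.222,0.592,0.537,-0.162,0.355,0.322,-0.270,0.065,-0.040,-0.275,-0.386,0.666
N,0.242,-0.468,-0.313,-0.351,0.214,-0.383,-0.396,-0.076,-0.331,0.457,0.422,-0.372,0.161,0.281,-0.176,-0.088,-0.065,-0.050,-0.096,0.462
D,0.191,-0.769,-0.351,-0.103,0.212,-0.312,-0.083,-0.056,-0.383,0.439,0.416,-0.720,0.277,0.218,-0.193,-0.013,-0.028,-0.133,-0.070,0.486
C,-0.186,0.342,0.214,0.212,-0.166,0.153,0.361,0.030,0.192,-0.188,-0.305,0.212,-0.267,-0.122,0.091,-0.055,0.028,0.224,0.127,-0.261
Q,0.130,-0.423,-0.383,-0.312,0.153,-0.372,-0.377,-0.103,-0.324,0.485,0.357,-0.405,0.256,0.281,-0.079,-0.140,-0.138,-0.041,-0.069,0.331
E,0.127,-0.878,-0.396,-0.083,0.361,-0.377,-0.151,0.008,-0.536,0.412,0.407,-0.722,0.270,0.203,-0.252,-0.054,-0.008,-0.107,0.073,0.449
G,0.033,-0.082,-0.076,-0.056,0.030,-0.103,0.008,-0.024,0.011,0.138,0.010,-0.097,-0.059,0.087,0.023,-0.042,-0.013,0.047,-0.010,0.083
H,0.223,-0.222,-0.331,-0.383,0.192,-0.324,-0.536,0.011,-0.291,0.398,0.385,-0.183,0.237,0.236,-0.106,-0.038,-0.068,-0.164,-0.145,0.425
I,-0.214,0.592,0.457,0.439,-0.188,0.485,0.412,0.138,0.398,-0.577,-0.522,0.459,-0.277,-0.416,0.177,0.138,0.137,0.110,0.158,-0.460
L,-0.207,0.537,0.422,0.416,-0.305,0.357,0.407,0.010,0.385,-0.522,-0.382,0.469,-0.218,-0.303,0.194,0.065,0.103,0.082,0.144,-0.464
K,0.265,-0.162,-0.372,-0.720,0.212,-0.405,-0.722,-0.097,-0.183,0.459,0.469,-0.067,0.320,0.273,-0.101,0.011,-0.115,-0.257,-0.317,0.430
M,-0.144,0.355,0.161,0.277,-0.267,0.256,0.270,-0.059,0.237,-0.277,-0.218,0.320,-0.083,-0.168,0.146,0.051,0.016,0.075,0.113,-0.326
F,-0.127,0.322,0.281,0.218,-0.122,0.281,0.203,0.087,0.236,-0.416,-0.303,0.273,-0.168,-0.281,0.077,0.072,0.111,0.056,0.100,-0.288
P,0.087,-0.270,-0.176,-0.193,0.091,-0.079,-0.252,0.023,-0.106,0.177,0.194,-0.101,0.146,0.077,-0.104,-0.010,-0.047,-0.126,-0.085,0.233
S,0.010,0.065,-0.088,-0.013,-0.055,-0.140,-0.054,-0.042,-0.038,0.138,0.065,0.011,0.051,0.072,-0.010,-0.040,-0.075,0.017,-0.069,0.019
T,0.058,-0.040,-0.065,-0.028,0.028,-0.138,-0.008,-0.013,-0.068,0.137,0.103,-0.115,0.016,0.111,-0.047,-0.075,0.021,0.035,-0.019,0.099
W,0.146,-0.275,-0.050,-0.133,0.224,-0.041,-0.107,0.047,-0.164,0.110,0.082,-0.257,0.075,0.056,-0.126,0.017,0.035,-0.052,-0.089,0.194
Y,0.046,-0.386,-0.096,-0.070,0.127,-0.069,0.073,-0.010,-0.145,0.158,0.144,-0.317,0.113,0.100,-0.085,-0.069,-0.019,-0.089,-0.046,0.102
V,-0.180,0.666,0.462,0.486,-0.261,0.331,0.449,0.083,0.425,-0.460,-0.464,0.430,-0.326,-0.288,0.233,0.019,0.099,0.194,0.102,-0.596
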