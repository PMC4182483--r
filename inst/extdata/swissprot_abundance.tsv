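aa	freq
A	0.08258258
C	0.01381381
D	0.05455455
E	0.06756757
F	0.03863864
G	0.07077077
H	0.02272272
I	0.05965966
K	0.05845846
L	0.09669670
M	0.02422422
N	0.04064064
P	0.04704705
Q	0.03933934
R	0.05535536
S	0.06566567
T	0.05345345
V	0.06876877
W	0.01081081
Y	0.02922923
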