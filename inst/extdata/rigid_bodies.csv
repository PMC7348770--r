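name,side,d12,d13,d23
head,,132.2,116.0,151.4
arm,R,99.0,92.1,134.0
arm,L,113.7,91.6,117.1
forearm,R,104.4,81.3,95.6
forearm,L,116.3,75.3,85.7
hand,R,128.2,69.4,146.3
hand,L,70.3,120.3,135.6
chest,,140.1,108.7,169.9
pelvis,,180.6,105.3,163.0
thigh,R,126.2,114.8,99.6
thigh,L,95.4,105.2,122.3
calf,R,95.5,109.7,75.7
calf,L,126.3,70.1,82.4
foot,R,63.9,107.0,83.1
foot,L,114.0,64.1,94.1
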