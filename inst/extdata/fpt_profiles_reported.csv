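factor_id,R,C,prominence,relation,group
F1,7.96,9.05,17,-1.09,Effect
F2,7.42,8.16,15.58,-0.73,Effect
F3,7.96,8.96,16.92,-1.01,Effect
F4,7.81,9.1,16.92,-1.29,Effect
F5,8.38,9.41,17.79,-1.03,Effect
F6,9.06,8.75,17.8,0.31,Cause
F7,8.72,8.94,17.66,-0.21,Effect
F8,8.48,8.65,17.14,-0.17,Effect
F9,8.57,8.64,17.21,-0.07,Effect
F10,9.46,8.42,17.88,1.04,Cause
F11,9.27,8.07,17.35,1.2,Cause
F12,8.56,7.72,16.28,0.84,Cause
F13,8.83,7.87,16.7,0.96,Cause
F14,8.34,7.79,16.13,0.56,Cause
F15,8.62,7.92,16.54,0.7,Cause
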