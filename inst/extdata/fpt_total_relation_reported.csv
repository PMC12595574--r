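,F1,F2,F3,F4,F5,F6,F7,F8,F9,F10,F11,F12,F13,F14,F15
F1,0.51,0.52,0.57,0.58,0.60,0.55,0.55,0.54,0.54,0.52,0.51,0.49,0.50,0.50,0.50
F2,0.54,0.43,0.54,0.55,0.56,0.51,0.52,0.50,0.50,0.49,0.47,0.45,0.46,0.46,0.46
F3,0.57,0.52,0.51,0.58,0.60,0.55,0.56,0.55,0.54,0.53,0.51,0.48,0.49,0.49,0.49
F4,0.57,0.51,0.57,0.50,0.60,0.54,0.55,0.53,0.53,0.52,0.49,0.47,0.48,0.48,0.48
F5,0.60,0.54,0.59,0.61,0.56,0.59,0.60,0.58,0.57,0.56,0.53,0.50,0.52,0.51,0.52
F6,0.66,0.59,0.65,0.66,0.68,0.56,0.65,0.62,0.61,0.60,0.57,0.55,0.56,0.55,0.56
F7,0.63,0.57,0.63,0.63,0.65,0.60,0.55,0.60,0.60,0.58,0.55,0.53,0.54,0.53,0.54
F8,0.60,0.54,0.59,0.60,0.64,0.59,0.61,0.52,0.59,0.57,0.55,0.52,0.53,0.52,0.53
F9,0.61,0.55,0.61,0.61,0.64,0.59,0.61,0.60,0.52,0.57,0.55,0.52,0.53,0.52,0.54
F10,0.67,0.60,0.66,0.67,0.70,0.65,0.67,0.65,0.65,0.56,0.61,0.59,0.60,0.59,0.60
F11,0.66,0.59,0.65,0.66,0.69,0.64,0.65,0.64,0.64,0.62,0.53,0.58,0.58,0.57,0.59
F12,0.61,0.55,0.60,0.61,0.62,0.59,0.61,0.58,0.59,0.57,0.55,0.47,0.55,0.53,0.55
F13,0.63,0.57,0.62,0.63,0.65,0.61,0.63,0.60,0.60,0.59,0.57,0.54,0.49,0.54,0.56
F14,0.60,0.54,0.59,0.61,0.62,0.58,0.58,0.56,0.56,0.56,0.54,0.51,0.52,0.46,0.52
F15,0.60,0.54,0.60,0.62,0.63,0.59,0.61,0.59,0.60,0.59,0.56,0.54,0.54,0.53,0.48
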