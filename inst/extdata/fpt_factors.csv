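"factor_id","label"
"F1","Resident needs"
"F2","Resident factor 2 (placeholder label)"
"F3","Residents' adherence"
"F4","Residents' trust level"
"F5","Professional identity of team members"
"F6","Professional competence of team members"
"F7","Teamwork"
"F8","FPT factor 8 (placeholder label)"
"F9","FPT factor 9 (placeholder label)"
"F10","Institutional management measures"
"F11","Resource allocation of personnel, finances, and materials"
"F12","IT infrastructure development"
"F13","Interdepartmental collaboration"
"F14","Government factor 14 (placeholder label)"
"F15","Supervision and management"
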