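category,mz,dz
MDD0CUD0|MDD0CUD0,298,277
MDD0CUD0|MDD0CUD1,28,73
MDD0CUD0|MDD1CUD0,114,145
MDD0CUD0|MDD1CUD1,17,35
MDD0CUD1|MDD0CUD1,16,10
MDD0CUD1|MDD1CUD0,6,21
MDD0CUD1|MDD1CUD1,16,23
MDD1CUD0|MDD1CUD0,47,33
MDD1CUD0|MDD1CUD1,12,18
MDD1CUD1|MDD1CUD1,11,5
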