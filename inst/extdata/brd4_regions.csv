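label,start,end
BD1,58,169
BD2,349,461
NPS,484,504
motifB,506,530
BID,531,579
ET,600,678
CPS,690,720
PDD,484,579
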