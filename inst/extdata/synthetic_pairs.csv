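subject_id,a,b,group
p01,0.10,0.12,child
p02,0.04,0.04,child
p03,0.30,0.26,child
p04,0.52,0.56,adult
p05,-0.04,-0.02,adult
p06,0.22,0.22,child
p07,0.74,0.70,adult
p08,0.16,0.20,adult
p09,0.08,0.06,child
p10,0.40,0.42,adult
p11,0.00,0.02,child
p12,0.60,0.58,adult
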