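hr,rbs,hpf,absence,occ_lt50,occ_50_70,occ_70_99,occ_100
+,+,+,1,3,4,12,1
+,+,-,1,1,0,1,0
+,-,+,0,3,0,1,0
+,-,-,18,17,4,16,0
-,,,7,2,0,4,0
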