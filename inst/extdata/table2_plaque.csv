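hr,rbs,hpf,absence,presence
+,+,+,1,20
+,+,-,1,2
+,-,+,0,4
+,-,-,18,37
-,,,7,6
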