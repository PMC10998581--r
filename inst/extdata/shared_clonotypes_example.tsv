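key	annotation_a	annotation_b
shared_01	TYPE1	TYPE1
shared_02	TYPE1	TYPE17
shared_03	TYPE1	TYPE17
shared_04	TYPE1	TYPE17
shared_05	TYPE1	TYPE17
shared_06	TYPE1	TYPE17
shared_07	TYPE1	TYPE17
shared_08	TYPE1	TYPE17
shared_09	TYPE1	TYPE17
shared_10	TYPE17	TYPE17
shared_11	TYPE17	TYPE17
shared_12	TYPE17	TYPE17
shared_13	TYPE17	TYPE17
shared_14	TYPE17	TYPE17
shared_15	TYPE17	TYPE1
shared_16	TYPE17	TYPE1
shared_17	TYPE17	TYPE1
shared_18	TYPE17	TYPE1
shared_19	TYPE17	TYPE1
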