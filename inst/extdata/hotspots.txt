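# hypervariable / mutational hotspot positions excluded from
# founder definitions, haplogroup scoring and clade dating
146
150
152
195
309
310
315
455
460
16093
16129
16182
16183
16189
16193
16311
16362
16519
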