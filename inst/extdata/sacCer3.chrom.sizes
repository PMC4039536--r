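chrI	230218
chrII	813184
chrIII	316620
chrIV	1531933
chrV	576874
chrVI	270161
chrVII	1090940
chrVIII	562643
chrIX	439888
chrX	745751
chrXI	666816
chrXII	1078177
chrXIII	924431
chrXIV	784333
chrXV	1091291
chrXVI	948066
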