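pop	Al-Subiya	Om Qaser	Al-Ritqa	Al-Shagaya	Al-Abraq	Al-Abdally
Al-Subiya	0	0.130	0.165	0.194	0.270	0.390
Om Qaser	0.130	0	0.094	0.135	0.238	0.365
Al-Ritqa	0.165	0.094	0	0.113	0.236	0.365
Al-Shagaya	0.194	0.135	0.113	0	0.138	0.352
Al-Abraq	0.270	0.238	0.236	0.138	0	0.447
Al-Abdally	0.390	0.365	0.365	0.352	0.447	0
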