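pop	Al-Subiya	Om Qaser	Al-Ritqa	Al-Shagaya	Al-Abraq	Al-Abdally
Al-Subiya	0	0.066	0.076	0.079	0.114	0.187
Om Qaser	0.066	0	0.052	0.058	0.103	0.173
Al-Ritqa	0.076	0.052	0	0.047	0.093	0.162
Al-Shagaya	0.079	0.058	0.047	0	0.050	0.129
Al-Abraq	0.114	0.103	0.093	0.050	0	0.092
Al-Abdally	0.187	0.173	0.162	0.129	0.092	0
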