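name	sources
Drugs	G;EC;St;Sc
Drug combinations	G;EC;St;Sc
Diseases	G;EC;St;Sc
Patients	G
Combination medications	G;EC;St;Sc
Behaviors	G;EC;St;Sc
Treatment methods	G;EC;St;Sc;EE
Research	G;St;Sc
Drug applications	G;EC;St;Sc;EE
Complications	G;EC;St;Sc
Contraindications	G;EC;St;Sc
Reports	G;St;Sc
Drug effects	G;EC;St;Sc;R;EE
Indications	G;EC;St;Sc
Symptoms	G;EC;St;Sc;R;EE
Drug contraindications	G;EC;St;Sc;R
Adverse reactions	G;EC;St;Sc;R
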