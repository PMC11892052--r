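indication_status,pct_contraindicated
indicated,56.2
offlabel,48.8
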