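gold: /nonexistent/gold.csv
superpixels: /tmp/Rtmp13BMEG/filed56e42f2e1/superpixels.csv
cues: /tmp/Rtmp13BMEG/filed56e42f2e1/cues
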