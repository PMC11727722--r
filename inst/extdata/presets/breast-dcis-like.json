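{"rad_cutoff": 300, "cost_ssc": 1, "alpha": 0.5, "method": "louvain", "refine": false}
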