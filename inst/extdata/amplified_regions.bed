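chr	274000	576000	acrAB_region
chr	4164000	4189000	rrlB_region
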