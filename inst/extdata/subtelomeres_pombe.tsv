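chrom	start	end
I	1	98950
I	5496300	5579133
II	1	96400
II	4437300	4539804
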