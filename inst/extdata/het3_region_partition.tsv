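name	chrom	start	end	markers
variability_zone	chr3L	22267604	23151844	pICon(79D);CkII/Vps
banded_80B-F	chr3L	23151844	unknown	CkII/Vps;unknown
gap_rich_banded_3L	unknown	unknown	unknown	unknown
satellite_block_region	unknown	unknown	unknown	unknown
gap_rich_banded_3R	unknown	unknown	unknown	unknown
distal_3R_border	unknown	unknown	unknown	unknown
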