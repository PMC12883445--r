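# Synthetic stand-in BED of chromosome X evolutionary strata and two
# ampliconic segments (hg38-like coordinates, approximate). These are
# placeholder intervals for demonstration and testing only: real analyses
# must supply their own annotation BED. 0-based half-open BED records.
chrX	2781478	46000000	XAR
chrX	46000000	88400000	XCR
chrX	88400000	93500000	XTR
chrX	93500000	153925834	XCR2
chrX	51000000	52000000	Ampliconic5
chrX	103000000	104000000	Ampliconic9
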