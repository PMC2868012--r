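region_id	start_anchor	start_offset	end_anchor	end_offset
upstream	TSS	-400	TSS	-100
promoter	TSS	-100	TSS	100
early	TSS	100	TSS	500
elongation	TSS	500	TTS	-100
termination	TTS	-100	TTS	100
downstream	TTS	100	TTS	400
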