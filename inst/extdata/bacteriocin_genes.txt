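# Bacteriocin-encoding gene families screened across L. delbrueckii strains
enterolysin_A
helveticin_J
bovicin_255
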