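band,images,identified_fins
excellent,1539,1204
average,978,761
poor,3477,NA
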