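metric	value
proteoforms_sec_sw480	5855
proteoforms_sec_sw620	6273
proteoforms_total_sw480	17316
proteoforms_total_sw620	14504
tp53_saav_basepeak_sw620	56000
tp53_saav_basepeak_sw480	7000
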