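sample,group,gene,ct
s1,control,snpfr,21.1
s1,control,rp49,17.9
s2,control,snpfr,21.6
s2,control,rp49,18.2
s3,control,snpfr,20.9
s3,control,rp49,17.8
s4,snpfr_rnai,snpfr,23.4
s4,snpfr_rnai,rp49,18
s5,snpfr_rnai,snpfr,23.9
s5,snpfr_rnai,rp49,18.3
s6,snpfr_rnai,snpfr,23.1
s6,snpfr_rnai,rp49,17.9
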