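# Lysis/lysogeny toggle of phage lambda: Cro and CI mutually inhibiting,
# with two activity levels each and three observation spots.
Cro:{low<high}
CI:{low<high}
Cro(low) -- CI(high)
CI(low) -- Cro(high)
obs_1:: Cro(high)
obs_2:: Cro(low)
obs_3:: CI(low)
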