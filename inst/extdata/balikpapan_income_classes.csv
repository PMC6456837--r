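lower,upper,median_midr,n_households,persons_per_household,total_persons,total_net_midr,usd_per_person_day
13,16,14.5,3,3,9,43.5,0.996
17,20,18.5,4,3,12,74,1.27
21,24,22.5,5,4,20,112.5,1.16
25,28,26.5,8,5,40,212,1.092
29,32,30.5,6,5,30,183,1.26
33,36,34.5,4,3,12,138,2.37
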