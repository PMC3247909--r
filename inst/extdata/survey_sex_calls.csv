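sn,sample_id,site,region,sex
1,SL49,SPNP,Shey,Female
2,SL54,SPNP,Shey,Female
3,SL55,SPNP,Shey,Female
4,SL57,SPNP,Shey,Male
5,SL64,SPNP,Dho,Female
6,SL42,KCA,Yagma,Male
7,SL34,KCA,Yagma,Female
8,SL28,KCA,Ghunsa,Male
9,SL25,KCA,Ghunsa,Female
10,SL3,KCA,Ghunsa,Female
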