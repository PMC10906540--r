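study,treatment,n,percent
Lee 2014,tofacitinib 5 mg,373,27.9
Lee 2014,MTX,186,14.0
Fleischmann 2015,baricitinib 4 mg,159,36
Fleischmann 2015,MTX,210,23
van Vollenhoven 2018,upadacitinib 15 mg,317,59.9
van Vollenhoven 2018,MTX,314,32.2
Westhovens 2019,filgotinib 200 mg,210,60.0
Westhovens 2019,MTX,416,46.2
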