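study,treatment,n,percent
Lee 2014,tofacitinib 5 mg,373,14.6
Lee 2014,MTX,186,7.6
Fleischmann 2015,baricitinib 4 mg,159,21
Fleischmann 2015,MTX,210,12
van Vollenhoven 2018,upadacitinib 15 mg,317,48.3
van Vollenhoven 2018,MTX,314,18.5
Westhovens 2019,filgotinib 200 mg,210,42.4
Westhovens 2019,MTX,416,29.1
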