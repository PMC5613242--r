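label,shell_residues,has_water,dE_aq
Compl1,3;7;11,0,-172.9
Compl2,3;4;7;11,0,-169.9
Compl3,3;7;9;11,0,-165.7
Compl4,3;7;11,1,-165.1
Compl5,3;7;11,0,-158.6
Compl6,1;3;7,1,NA
Compl7,1;3;11,0,NA
Compl8,,0,NA
Compl9,7;11,1,NA
Compl10,,1,NA
Compl11,,1,NA
Compl12,,1,NA
Compl13,,1,NA
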