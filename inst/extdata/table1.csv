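model,carb,n_ligand,charge,dE,dH298
4CWA,4M,6,-1,-124.8,-126.1
4CWH,4M,6,-1,-124.1,-125.5
4CW,3M1B,5,-1,-120.7,-125.0
4CW,4M,5,-1,-117.1,-120.4
4CH,3M1B,5,-1,-114.0,-117.8
4C2A,4M,6,-1,-115.0,-117.4
3CWHA,3M,6,0,-115.7,-116.9
4C2H,4M,6,-1,-114.8,-116.5
4CA,4M,5,-1,-112.3,-115.6
4CA,3M1B,5,-1,-112.0,-115.1
3C2WH,3M,6,0,-112.8,-113.7
3C2HA,3M,6,0,-112.1,-113.6
4C,4M,4,-1,-108.6,-113.4
4C,2M2B,4,-1,-108.6,-113.3
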