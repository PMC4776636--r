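PTV: D(%)95(%), D(Gy)95(%), Dmax, Dmean/Rx × 100
Lungs: V(%)20(Gy), V(%)5(Gy), Dmean
Heart: V(%)30(Gy), Dmean
Esophagus: Dmean, Dmax
SpinalCord: Dmax
BrachialPlexus: Dmax, D(Gy)0.03(cc)
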