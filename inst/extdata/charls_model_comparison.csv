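model,map,mrr
GCN,0.3891,0.2980
GCN-LSTM,0.4304,0.2000
EvolveGCN,0.3619,0.3112
Graphormer,0.4257,0.2500
CE-GCN,0.4387,0.3733
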