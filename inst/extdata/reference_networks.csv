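organism,layer,n_nodes,n_edges,mean_degree,median_degree,max_degree,soma_size_um,contact_threshold_nm
fly,synaptic,16804,1936798,230.52,195,3097,2.47,40
fly,contact,16804,7747751,922.13,806,7335,2.47,40
mouse,synaptic,6548,111636,34.10,23,881,5.34,41
mouse,contact,6548,1373875,419.63,418,2042,5.34,41
human,synaptic,15730,74934,9.53,6,138,7.6,46
human,contact,15730,2049143,260.54,188.5,1221,7.6,46
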