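{"design_id":"DDC-1","grid_rows":5,"grid_cols":5,"address_rows":1,"n_edge_staples":13,"overhang_domain_ids":["dom1","dom2","dom3","dom4","dom5","dom6","dom7","dom1","dom2","dom3","dom4","dom5","dom6"],"domain_seqs":["CCCTCTAACCATCACA","GTGCCTCCCCTTCGCA","CTTGAACCGGGACGAC","ACCGCTTGCCCGTGGA","TCCCCATGTGAACTAC","CTATGCGCGCAGTTGA","TCGAAAGTTGTTGAAG"],"gap_region_seqs":["CATTCATAACCTCGTG","TAACACAACGTGTAGG"],"n_gaps":2,"scaffold_id":"synM13-1","breakpoint":0,"pitch_off":[6,6],"pitch_on":[6,12],"marker_sites":[[0,-2],[2,-2]],"schema":"ddc-design/1"}
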