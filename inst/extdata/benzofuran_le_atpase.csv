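compound_id,le_dmrs_atp_only,sd_dmrs_atp_only,le_complex_clusters,sd_complex_clusters,le_complex_snapshots,sd_complex_snapshots,atpase_rate
1,-0.24,0.02,-0.24,0.04,-0.24,0.04,1.24
4,-0.25,0.03,-0.25,0.03,-0.25,0.03,2.27
10,-0.28,0.05,-0.23,0.04,-0.23,0.05,2.74
12,-0.28,0.01,-0.29,0.03,-0.28,0.03,2.35
16,-0.21,0.04,-0.23,0.03,-0.26,0.03,1.17
18,-0.30,0.03,-0.30,0.03,-0.30,0.04,4.01
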