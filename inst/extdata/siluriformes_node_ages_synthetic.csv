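clade_tips,age_ma,source
Loricariidae;Diplomystidae,146.7,reported
Diplomystidae;Bagridae,142.2,reported
Nematogenyidae;Loricariidae,123.8,reported
Nematogenyidae;Trichomycteridae,114.0,reported
Callichthyidae;Loricariidae,117.2,reported
Loricariidae;Astroblepidae,97.4,reported
Scoloplacidae;Astroblepidae,92.1,reported
Doradidae;Bagridae,135,interpolated_synthetic
Doradidae;Pimelodidae,120,interpolated_synthetic
Doradidae;Aspredinidae,100,interpolated_synthetic
Doradidae;Auchenipteridae,75,interpolated_synthetic
Pseudopimelodidae;Pimelodidae,95,interpolated_synthetic
Pimelodidae;Heptapteridae,80,interpolated_synthetic
Ariidae;Bagridae,128,interpolated_synthetic
Amphiliidae;Bagridae,122,interpolated_synthetic
Schilbeidae;Bagridae,116,interpolated_synthetic
Mochokidae;Bagridae,110,interpolated_synthetic
Ictaluridae;Bagridae,103,interpolated_synthetic
Sisoridae;Bagridae,96,interpolated_synthetic
Sisoridae;Akysidae,85,interpolated_synthetic
Sisoridae;Erethistidae,65,interpolated_synthetic
Akysidae;Amblycipitidae,67,interpolated_synthetic
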