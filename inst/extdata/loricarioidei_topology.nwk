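(((Nematogenyidae,Trichomycteridae),(Callichthyidae,(Loricariidae,(Scoloplacidae,Astroblepidae)))),(Diplomystidae,((((Doradidae,Auchenipteridae),Aspredinidae),(Pseudopimelodidae,(Pimelodidae,Heptapteridae))),(Ariidae,(Amphiliidae,(Schilbeidae,(Mochokidae,(Ictaluridae,(((Sisoridae,Erethistidae),(Akysidae,Amblycipitidae)),Bagridae)))))))));
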