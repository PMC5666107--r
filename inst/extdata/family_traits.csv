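family,head_odontodes,trunk_odontodes,trunk_plates
Loricariidae,present,present,present
Astroblepidae,present,present,absent
Scoloplacidae,present,present,present
Callichthyidae,present,present,present
Trichomycteridae,present,absent,absent
Nematogenyidae,absent,present,absent
Diplomystidae,absent,absent,absent
Doradidae,absent,absent,present
Auchenipteridae,absent,absent,absent
Aspredinidae,absent,absent,present
Pseudopimelodidae,absent,absent,absent
Pimelodidae,absent,absent,absent
Heptapteridae,absent,absent,absent
Ariidae,absent,absent,absent
Amphiliidae,absent,absent,present
Schilbeidae,absent,absent,absent
Mochokidae,absent,absent,absent
Ictaluridae,absent,absent,absent
Sisoridae,absent,absent,present
Erethistidae,absent,absent,absent
Akysidae,absent,absent,absent
Amblycipitidae,absent,absent,absent
Bagridae,absent,absent,absent
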