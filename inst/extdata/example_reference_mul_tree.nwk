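(((((Nymphaea_mexicana:5,Nymphaea_tetragona:5):25,((Nymphaea_gigantea_Albert:5,Nymphaea_gigantea_Hybrid1:5):20,((((Nymphaea_colorata:5,A-Nymphaea_Midnight:5):5,A-Nymphaea_Woods_blue_goddess:10):5,((Nymphaea_caerulea:5,B-Nymphaea_Midnight:5):5,B-Nymphaea_Woods_blue_goddess:10):5):5,((Nymphaea_potamophila:10,(Nymphaea_prolifera:5,Nymphaea_rubra:5):5):5,(Victoria_cruziana:5,Euryale_ferox:5):10):5):5):5):5,(Nuphar_lutea:5,Nuphar_advena:5):30):5,(Cabomba_caroliniana:5,Brasenia_schreberi:5):35):5,Amborella_trichopoda:45);
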