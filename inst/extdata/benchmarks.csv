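id,compressed,length,n_hydrophobic,note
HI 1,HPH2P2H4PH3P2H2P2HPH3PHPH2P2H2P3HP8H2,48,24,Harvard instance
HI 2,H4PH2PH5P2HP2H2P2HP6HP2HP3HP2H2P2H3PH,48,24,Harvard instance
HI 3,PHPH2PH6P2HPHP2HPH2PHPHP3HP2H2P2H2P2HPHP2HP,48,24,Harvard instance
HI 4,PHPH2P2HPH3P2H2PH2P3H5P2HPH2PHPHP4HP2HPHP,48,24,Harvard instance
HI 5,P2HP3HPH4P2H4PH2PH3P2HPHPHP2HP6H2PH2PH,48,24,Harvard instance
HI 6,H3P3H2PHPH2PH2PH2PHP7HPHP2HP3HP2H6PH,48,24,Harvard instance
HI 7,PHP4HPH3PHPH4PH2PH2P3HPHP3H3P2H2P2H2P3H,48,24,Harvard instance
HI 8,PHPHPH4PHP6HPHPHPHPHPHPHP,48,24,Harvard instance (run-length string incompletely recovered)
HI 9,PHPHP4HPHPHPHPH6PHPHPHPHPHPH3P4H,48,24,Harvard instance (run-length string incompletely recovered)
HI 10,PHP6HPHPHPHPHPHPHPHPH7PH,48,24,Harvard instance (run-length string incompletely recovered)
HI 9/2,PHPHP4HPHPHPHPH6P2,24,12,First half of HI 9
F 90,PHPHP4HPH6PHPHPHPH5PHPHPH4PHP4HPHPHPHPHPHPHPHP4HPHP,90,50,90-mer benchmark (run-length string incompletely recovered)
S 1,H4PH6PHPH8PHPH10PHP5HPH8PHPHP3H8PH6PH7PHPH9PHPH7PHPH7PH4,135,100,135-mer benchmark (run-length string incompletely recovered)
S 4,H8PHPH3PH5PH6PHPHPHPHPHPH7PHPHPH6PHPHPHP,164,100,164-mer benchmark (run-length string incompletely recovered)
R 1,P8HPHPHPHPHPHPHPHP4H6PHP5HPHP,200,100,200-mer benchmark (run-length string incompletely recovered)
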