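MEME version 4

ALPHABET= ACGU

strands: +

Background letter frequencies
A 0.25 C 0.25 G 0.25 U 0.25

MOTIF CPEB_demo_1 CPEB_demo
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880
 0.880 0.040 0.040 0.040
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880

MOTIF CPEB_demo_2 CPEB_demo
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880
 0.880 0.040 0.040 0.040
 0.880 0.040 0.040 0.040
 0.040 0.040 0.040 0.880
 0.040 0.040 0.040 0.880

MOTIF PCBP_demo_1 PCBP_demo
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.040 0.880 0.040 0.040
 0.040 0.880 0.040 0.040
 0.040 0.880 0.040 0.040
 0.040 0.040 0.040 0.880
 0.040 0.880 0.040 0.040
 0.040 0.880 0.040 0.040
 0.040 0.880 0.040 0.040

MOTIF RBFOX_demo_1 RBFOX_demo
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.040 0.040 0.040 0.880
 0.040 0.040 0.880 0.040
 0.040 0.880 0.040 0.040
 0.880 0.040 0.040 0.040
 0.040 0.040 0.040 0.880
 0.040 0.040 0.880 0.040
 0.040 0.040 0.040 0.880

MOTIF SRSF_demo_1 SRSF_demo
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.040 0.040 0.880 0.040
 0.040 0.040 0.880 0.040
 0.880 0.040 0.040 0.040
 0.040 0.040 0.880 0.040
 0.040 0.040 0.880 0.040
 0.880 0.040 0.040 0.040
 0.040 0.040 0.880 0.040

MOTIF QKI_demo_1 QKI_demo
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.880 0.040 0.040 0.040
 0.040 0.880 0.040 0.040
 0.040 0.040 0.040 0.880
 0.880 0.040 0.040 0.040
 0.880 0.040 0.040 0.040
 0.040 0.880 0.040 0.040
 0.880 0.040 0.040 0.040
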