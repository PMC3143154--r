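>SBE_SYNTH
A [ 1 1 1 1 97 1 97 1 ]
C [ 1 1 97 1 1 1 1 97 ]
G [ 97 1 1 1 1 97 1 1 ]
T [ 1 97 1 97 1 1 1 1 ]
>MOTIF_01
A [ 61 66 65 66 15 17 ]
C [ 14 16 16 15 63 17 ]
G [ 13 13 14 13 17 16 ]
T [ 19 17 14 13 19 61 ]
>MOTIF_02
A [ 18 14 14 16 66 14 16 ]
C [ 15 16 17 61 13 65 15 ]
G [ 19 16 63 14 17 18 18 ]
T [ 65 65 17 15 14 14 64 ]
>MOTIF_03
A [ 13 14 16 17 17 14 65 60 ]
C [ 66 13 60 64 63 13 19 16 ]
G [ 16 64 15 16 18 14 17 19 ]
T [ 17 16 15 18 14 64 16 14 ]
>MOTIF_04
A [ 18 16 65 64 17 19 14 17 ]
C [ 63 13 15 19 65 14 13 13 ]
G [ 17 60 13 18 17 62 15 15 ]
T [ 13 17 14 13 13 14 60 66 ]
>MOTIF_05
A [ 18 60 18 19 19 16 13 13 18 ]
C [ 17 14 65 65 14 65 13 16 18 ]
G [ 13 19 18 16 61 16 14 62 61 ]
T [ 65 14 18 16 19 14 61 17 16 ]
>MOTIF_06
A [ 13 18 13 14 15 62 16 13 66 13 ]
C [ 60 18 17 19 63 15 16 60 18 64 ]
G [ 17 63 15 66 14 18 15 18 16 16 ]
T [ 15 14 65 17 13 16 60 17 19 13 ]
>MOTIF_07
A [ 66 63 16 18 19 15 ]
C [ 15 13 19 66 13 14 ]
G [ 17 18 17 14 60 17 ]
T [ 17 15 66 19 13 66 ]
>MOTIF_08
A [ 18 15 18 65 64 14 65 14 ]
C [ 13 13 18 19 15 13 13 19 ]
G [ 17 18 63 14 19 18 15 14 ]
T [ 65 61 19 17 17 60 16 61 ]
>MOTIF_09
A [ 15 16 15 13 62 16 65 ]
C [ 65 14 16 19 13 17 13 ]
G [ 17 14 18 66 15 63 18 ]
T [ 18 60 61 14 15 14 15 ]
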