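>SYN01 synthetic_motif_1
A [ 8 7 6 6 88 8 5 3 82 8 6 ]
C [ 7 5 3 84 3 87 5 90 6 4 6 ]
G [ 82 84 6 6 4 1 87 6 6 5 84 ]
T [ 3 4 85 4 5 4 3 1 6 83 4 ]
>SYN02 synthetic_motif_2
A [ 6 1 85 2 8 9 84 82 ]
C [ 1 5 4 90 6 4 5 7 ]
G [ 8 9 5 4 83 3 7 6 ]
T [ 85 85 6 4 3 84 4 5 ]
>SYN03 synthetic_motif_3
A [ 3 6 5 4 84 3 86 5 3 6 ]
C [ 84 89 7 7 2 6 1 80 85 5 ]
G [ 7 3 83 85 5 4 6 8 7 83 ]
T [ 6 2 5 4 9 87 7 7 5 6 ]
>SYN04 synthetic_motif_4
A [ 82 6 8 4 6 3 9 5 ]
C [ 3 0 86 85 5 85 5 0 ]
G [ 7 5 4 7 83 9 4 88 ]
T [ 8 89 2 4 6 3 82 7 ]
>SYN05 synthetic_motif_5
A [ 7 85 84 4 5 8 6 6 5 86 ]
C [ 5 5 6 85 6 7 87 7 7 5 ]
G [ 84 1 7 6 4 2 4 85 82 3 ]
T [ 4 9 3 5 85 83 3 2 6 6 ]
>SYN06 synthetic_motif_6
A [ 2 86 8 6 4 3 6 85 3 3 4 85 ]
C [ 86 6 3 4 6 2 7 3 5 84 5 3 ]
G [ 7 3 83 86 6 5 84 6 5 8 85 8 ]
T [ 5 5 6 4 84 90 3 6 87 5 6 4 ]
>SYN07 synthetic_motif_7
A [ 5 8 4 88 4 3 2 86 ]
C [ 6 86 7 5 4 83 86 6 ]
G [ 6 2 6 2 87 4 4 6 ]
T [ 83 4 83 5 5 10 8 2 ]
>SYN08 synthetic_motif_8
A [ 85 3 85 5 2 85 7 5 7 ]
C [ 7 85 4 86 6 4 4 8 3 ]
G [ 4 9 4 4 88 6 83 83 4 ]
T [ 4 3 7 5 4 5 6 4 86 ]
>SYN09 synthetic_motif_9
A [ 2 3 11 7 2 3 83 8 4 87 85 ]
C [ 5 5 4 5 6 86 4 3 85 2 6 ]
G [ 86 2 1 84 83 5 6 3 2 6 5 ]
T [ 7 90 84 4 9 6 7 86 9 5 4 ]
>SYN10 synthetic_motif_10
A [ 83 5 3 3 83 4 4 3 ]
C [ 5 3 89 7 8 5 5 10 ]
G [ 9 88 6 5 4 5 83 83 ]
T [ 3 4 2 85 5 86 8 4 ]
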