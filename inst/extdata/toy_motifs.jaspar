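>TOY01 TOYTF01
A [ 150 150 997 150 150 150 ]
C [ 150 550 1 550 550 550 ]
G [ 150 150 1 150 150 150 ]
T [ 550 150 1 150 150 150 ]
>TOY02 TOYTF02
A [ 550 150 1 150 150 150 ]
C [ 150 550 1 150 150 550 ]
G [ 150 150 1 150 550 150 ]
T [ 150 150 997 550 150 150 ]
>TOY03 TOYTF03
A [ 150 150 150 997 150 150 150 ]
C [ 150 150 550 1 150 150 150 ]
G [ 150 550 150 1 150 150 150 ]
T [ 550 150 150 1 550 550 550 ]
>TOY04 TOYTF04
A [ 150 150 550 1 150 150 550 ]
C [ 550 150 150 1 550 150 150 ]
G [ 150 550 150 997 150 550 150 ]
T [ 150 150 150 1 150 150 150 ]
>TOY05 TOYTF05
A [ 150 550 550 997 550 150 150 150 ]
C [ 150 150 150 1 150 150 150 150 ]
G [ 550 150 150 1 150 150 550 150 ]
T [ 150 150 150 1 150 550 150 550 ]
>TOY06 TOYTF06
A [ 550 550 150 997 150 550 550 150 ]
C [ 150 150 150 1 150 150 150 550 ]
G [ 150 150 150 1 150 150 150 150 ]
T [ 150 150 550 1 550 150 150 150 ]
>TOY07 TOYTF07
A [ 150 150 150 550 1 150 150 150 150 150 ]
C [ 150 550 150 150 1 150 150 150 150 550 ]
G [ 150 150 150 150 1 150 150 550 150 150 ]
T [ 550 150 550 150 997 550 550 150 550 150 ]
>TOY08 TOYTF08A::TOYTF08B
A [ 550 150 150 550 1 150 150 550 150 150 ]
C [ 150 150 550 150 1 150 150 150 550 150 ]
G [ 150 150 150 150 1 550 150 150 150 150 ]
T [ 150 550 150 150 997 150 550 150 150 550 ]
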