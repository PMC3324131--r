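# ddI resistance panel (RT amino-acid coordinates)
M41L
D67N
T69D
K70R
L74V
V118I
M184VI
L210W
T215Y/F
K219Q/E
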