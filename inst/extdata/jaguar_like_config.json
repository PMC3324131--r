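{"n":102,"prevalences":[0.48,0.343,0.088,0.265,0.088,0.186,0.922,0.275,0.539,0.245],"labels":["M41L","D67N","T69D","K70R","L74V","V118I","M184V/I","L210W","T215Y/F","K219Q/E"],"correlation":null,"effects":[0.3,0.15,0.1,0.2,0.4,0.1,0.25,0.15,0.3,0.1],"interactions":[],"intercept":-1.33,"noise_sd":0.735,"censor_floor":-1.53,"seed":null}
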