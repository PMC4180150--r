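(Wallaby:1,(((Armadillo:1,Sloth:1):1,Elephant:1):1,(((Cavia:1,Rabbit:1):1,(Treeshrew:1,((MouseLemur:1,Otolemur:1):1,(Tarsius:1,(Callitrix:1,(Gibbon:1,(Pongo:1,Gorilla:1):1):1):1):1):1):1):1,(Hedgehog:1,(Bat:1,((Horse:1,Panda:1):1,(Alpaca:1,(Pig:1,(Cow:1,Dolphin:1):1):1):1):1):1):1):1):1);
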