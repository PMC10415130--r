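kag = -0.6*(kcg - kgc + kat - kta + kct - 1.3*ktc - kga - 0.6)
kga = 0.7*(kcg - kgc + kat - kta + kct - ktc + kag + 0.1)
ktc = 0.8*(0.7*kcg - kgc + 0.8*kat - kta + kag - 0.8*kga + kct + 0.4)
kct = -0.8*(kcg - kgc + 0.8*kat - kta + kag - kga + 0.1*kca - ktc - 0.3)
kac = -0.8*(kgc - kcg + kat - kta + kgt - ktg - kca - 0.3)
kca = 0.8*(kgc - kcg + kat - kta + kgt - ktg + kac + 0.2)
kgt = -0.8*(kgc - kcg + kat - kta - ktg + kac - kca - 0.2)
ktg = 0.8*(kgc - kcg + kat - kta + kgt + kac - kca + 0.1)
kat = -0.5*(-2*kta + kct - ktc + kag - kga + kgt - ktg + kac - kca - 0.5)
kta = 0.5*(2*kat + kct - ktc + kag - kga + kgt - ktg + kac - kca - 0.1)
kgc = -0.4*(-2*kcg + ktc - kct + kga - kag + kgt - ktg + kac - kca - 0.06)
kcg = 0.4*(2*kgc + ktc - kct + kga - kag + kgt - ktg + kac - kca + 0.9)
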