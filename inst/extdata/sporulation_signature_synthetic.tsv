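gene
spo0A
spoIIA
spoIIIA
spoIVA
spoVA
spoVIA
spo0B
spoIIB
spoIIIB
spoIVB
spoVB
spoVIB
spo0D
spoIID
spoIIID
spoIVD
spoVD
spoVID
spo0E
spoIIE
spoIIIE
spoIVE
spoVE
spoVIE
spo0G
spoIIG
spoIIIG
spoIVG
spoVG
spoVIG
spo0J
spoIIJ
spoIIIJ
spoIVJ
spoVJ
spoVIJ
spo0M
spoIIM
spoIIIM
spoIVM
spoVM
spoVIM
spo0P
spoIIP
spoIIIP
spoIVP
spoVP
spoVIP
spo0Q
spoIIQ
spoIIIQ
spoIVQ
spoVQ
spoVIQ
spo0R
spoIIR
spoIIIR
spoIVR
spoVR
spoVIR
spo0T
spoIIT
spoIIIT
spoIVT
spoVT
spoVIT
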