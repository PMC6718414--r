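term	bin
endoplasmic reticulum	secretory
er	secretory
golgi apparatus	secretory
golgi	secretory
proteasome	secretory
lysosome	secretory
extracellular	secretory
extracellular space	secretory
secreted	secretory
mitochondria	mitochondria
mitochondrion	mitochondria
mitochondrial	mitochondria
nucleus	nucleus
nuclear	nucleus
chromosome	nucleus
cytoplasm	cytoplasm
cytosol	cytoplasm
cytoskeleton	cytoplasm
ribosome	cytoplasm
ribosomes	cytoplasm
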