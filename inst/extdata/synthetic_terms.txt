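# Synthetic, invented medical-term-like strings (no real patient-derived
# text; several are not real words at all). One term per line; terms may
# contain a space.
koorts
hoesten
buikpijn
hoofdpijn
misselijkheid
duizeligheid
kortademigheid
pijnklachten
flebralgie
cardiopathie
neurodynie
gastromalgie
dermatose
pulmonitis
nefralgie
hepatomie
artrodynie
myalgitis
osteopenose
tachyflexie
bradypnoom
hypertensie
oedeem
exantheem
cyanose
icterus
anemie
trombose
pneumonitis
bronchospasme
laryngitis
sinusopathie
otalgie
conjunctivose
retinopathie
glaucomie
cataractose
stomatitis
gingivose
oesofagie
gastritis
enteropathie
colitis
proctalgie
cystitis
uretropathie
prostatose
endometriose
mastopathie
lymfadenie
splenomie
pancreatose
thyreopathie
adrenalgie
neuropathie
radiculose
myelopathie
encefalgie
meningose
vasculitis
acute flebralgie
chronische neurodynie
milde dermatose
ernstige pulmonitis
recidief trombose
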