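name,formula
akebia saponin B,C40H64O12
apigenin,C15H10O5
astraisoflavan,C17H18O5
astraisoflavan-7-O-beta-d-glucoside,C23H28O10
calycosin,C16H12O5
calycosin-7-O-beta-d-glucoside,C22H22O10
carasinaurone,C16H14O6
daidzein,C15H10O4
equol,C15H14O3
formononetin,C16H12O4
genkwanin,C16H12O5
methylnissolin,C17H16O5
stachydrine,C7H13NO2
"2',4',7-trihydroxyisoflavan",C15H14O4
"7,3',4'-trihydroxyisoflavanone",C15H12O5
"7-hydroxy-2',3',4'-trimethoxyisoflavan",C18H20O5
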