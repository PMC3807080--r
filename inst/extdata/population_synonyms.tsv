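synonym	canonical
European	European
European American	European
European Australian	European
European New Zealander	European
West European	European
North European	European
South European	European
East European	European
Caucasian	European
EastAsian	EastAsian
WestAsian	WestAsian
SouthAsian	SouthAsian
SouthAmerican	SouthAmerican
CentralAmerican	CentralAmerican
NorthAfrican	NorthAfrican
SouthAfrican	SouthAfrican
AfricanAmerican	AfricanAmerican
East Asian	EastAsian
South-East Asian	EastAsian
Southeast Asian	EastAsian
West Asian	WestAsian
South Asian	SouthAsian
South American	SouthAmerican
Central American	CentralAmerican
North African	NorthAfrican
South African	SouthAfrican
African American	AfricanAmerican
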