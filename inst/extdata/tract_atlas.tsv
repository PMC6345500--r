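name	hemisphere	category	cells	provenance
CC-genu	midline	commissural	A2C2S1;A3C2S1	main-text
CC-body	midline	commissural	A2C2S2;A3C2S2	inferred
CC-splenium	midline	commissural	A2C2S3;A3C2S3	inferred
AC	midline	commissural	A2C2S2;A3C2S2;A2C2S3;A3C2S3	main-text
Fo	midline	commissural	A2C2S2;A3C2S2;A2C2S3;A3C2S3	inferred
IC	R	projection	A2C2S2;A2C2S3	inferred
IC	L	projection	A3C2S2;A3C2S3	inferred
ExC	R	projection	A2C2S2	main-text
ExC	L	projection	A3C2S2	main-text
CST	R	projection	A2C1S2;A2C2S2;A2C2S3;A2C3S3	inferred
CST	L	projection	A3C1S2;A3C2S2;A3C2S3;A3C3S3	inferred
OR	R	projection	A1C2S3;A1C2S4;A2C2S4	inferred
OR	L	projection	A4C2S3;A4C2S4;A3C2S4	inferred
ATR	R	projection	A2C2S1;A2C2S2	main-text
ATR	L	projection	A3C2S1;A3C2S2	main-text
Ci	R	associative	A2C2S1;A2C2S2;A2C2S3;A2C3S3	main-text
Ci	L	associative	A3C2S1;A3C2S2;A3C2S3;A3C3S3	main-text
ILF	R	associative	A1C3S2;A1C3S3;A1C2S4	inferred
ILF	L	associative	A4C3S2;A4C3S3;A4C2S4	inferred
MLF	R	associative	A1C2S2;A1C2S3	main-text
MLF	L	associative	A4C2S2;A4C2S3	main-text
IFOF	R	associative	A2C2S1;A2C2S2;A2C2S3;A2C3S3;A2C2S4	main-text
IFOF	L	associative	A3C2S1;A3C2S2;A3C2S3;A3C3S3;A3C2S4	main-text
UF	R	associative	A2C2S1;A2C2S2;A2C3S2	main-text
UF	L	associative	A3C2S1;A3C2S2;A3C3S2	main-text
FAT	R	associative	A1C2S1;A1C2S2;A2C1S1	main-text
FAT	L	associative	A4C2S1;A4C2S2;A3C1S1	main-text
SLF-h	R	associative	A1C1S2;A1C2S2;A1C2S3	main-text
SLF-h	L	associative	A4C1S2;A4C2S2;A4C2S3	main-text
SLF-v	L	associative	A4C2S3;A4C3S3	inferred; counted once to match the published 34-structure inventory
AF	R	associative	A1C2S2;A1C2S3;A1C3S3	main-text
AF	L	associative	A4C2S2;A4C2S3;A4C3S3	main-text
VOF	R	associative	A1C2S4;A1C3S4	inferred
VOF	L	associative	A4C2S4;A4C3S4	inferred
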