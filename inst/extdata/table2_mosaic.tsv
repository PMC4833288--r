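tissue	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16
Intestine (E)	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Spermatheca A (MSpppapp)	-	-	-	-	-	+	-	-	-	-	-	-	+	-	-	-
Spermatheca P (MSappaap)	-	-	-	-	-	+	-	-	-	-	-	-	+	-	-	-
Gonad sheath A (Mspppapp)	-	-	-	-	-	+	-	-	-	-	-	-	+	-	-	-
Gonad sheath P (Msappaap)	-	-	-	-	-	+	-	-	-	-	-	-	+	-	-	-
Lateral hypodermis (ABa, ABp, C)	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Ventral hypodermal ridge (ABp)	+	+	+	+	+	+	+	+	+	+	+	-	+	+	+	+
Excretory canal (ABplpa)	+	-	-	+	+	+	+	+	-	-	+	-	+	+	+	+
Procorpus (4 ABa/2 MS)	+/-	+/-	+/-	+/-	+/-	+	+/-	+/-	+/-	+/-	+	-	+	+/-	+/-	+/-
Metacorpus (5 MS/1 ABar)	-	-	-	-	-	+	-	-	-	-	+	-	+	-	-	-
Isthmus (4 MS/2 ABaraa)	-/+	-/+	-/+	-/+	-/+	+	-/+	-/+	-/+	-/+	+	-	+	-/+	-/+	-/+
Posterior bulb (MS)	-	-	-	-	-	+	-	-	-	-	+	-	+	-	-	-
Hyp 10 (AB)	+	+	-	+	+	-	+	+	+	+	-	-	+	+	-	+
Body wall muscles Head (MS)	+	-	+	+	-	-	-	-	-	-	+	-	+	-	-	-
Body wall muscles Mid (D)	-	-	-	-	-	-	-	-	-	-	+	-	+	-	-	-
Body wall muscles Posterior (C)	+	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-
VC2-6 neurons (ABp)	-	+	-	-	+	-	+	+	-	+	-	-	-	-	-	-
Head ganglion neurons (mostly ABp)	-/+	+/-	-/+	-/+	+/-	-/+	-/+	-/+	+/-	+/-	-/+	-/+	-/+	-/+	-/+	-/+
Ventral nerve cord neurons (mostly ABp)	-/+	+/-	-/+	-/+	+/-	-/+	-/+	-/+	+/-	+/-	-/+	-/+	-/+	-/+	-/+	-/+
Likely missing from	E, D, MS	P1	E, C, D, most MS	E, D, most MS	P1	E, C, D	P1	P1	P1	P1	E, C	P1, most ABa?	E, C	P1	P1	P1
Present in	ABa, ABp, C	ABa, ABp	ABa, ABp	ABa, ABp, C	ABa, ABp	ABa, ABp MSa, MSp	ABa, ABp	ABa, ABp	ABa, ABp	ABa, ABp	ABa, ABp, D, MS	ABp	ABa, ABp, D, MS	ABa, ABp	ABa, ABp	ABa, ABp
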