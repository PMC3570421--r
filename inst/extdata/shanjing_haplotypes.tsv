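lineage	population_id	n	haplotypes
A	JP	10	H1:2;H2:2;H3:5;H4:1
A	LC	12	H5:4;H6:3;H7:1;H8:3;H9:1
A	ZB	1	H10:1
B	PL	10	H26:9;H27:1
B	SHZ	10	H28:8;H29:2
C	GF	8	H43:5;H44:2;H45:1
C	PM	14	H43:7;H45:5;H46:2
C	GY	1	H55:1
D	WBL	4	H11:1;H12:3
D	SB	13	H13:10;H14:2;H15:1
D	JD	10	H13:7;H16:1;H17:1;H18:1
D	NJ	1	H19:1
D	DY	14	H13:4;H20:1;H21:3;H22:1;H23:3;H24:1;H25:1
D	YD	13	H30:2;H31:5;H32:1;H33:3;H34:1;H35:1
D	CJ	5	H36:1;H37:1;H38:1;H39:1;H40:1
D	SJ	4	H41:3;H42:1
D	LL	13	H47:2;H48:2;H49:1;H50:2;H51:3;H52:1;H53:1;H54:1
D	MC	2	H56:1;H57:1
D	HS	1	H58:1
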