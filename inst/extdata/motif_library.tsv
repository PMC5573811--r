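name	subfamily	pattern
RRX8W	generic	RRX8W
RDR	generic	R(D/N)R
DDXXD	generic	DDXXD
NSE/DTE	generic	(D/N)D(V/M/L/I)X(S/T)XXXE
RRX8W	TPS-a	R(P/R)X(A/S)X(F/Y)HP(S/T/N)(I/L)W
RDR	TPS-a	R(D/N)R
DDXXD	TPS-a	DD(I/T)(Y/F)D
NSE/DTE	TPS-a	(D/N)D(I/M/V)X(S/T/G)(H/Y)(K/E)(F/V)E
RRX8W	TPS-b	R(R/Q)SA(N/D)YXP(S/T/N)IW
RDR	TPS-b	R(D/N)(R/S)
DDXXD	TPS-b	DD(I/V)YD
NSE/DTE	TPS-b	(D/N)DL(G/A)TSSDE
DDXXD	TPS-g	DDIFD
NSE/DTE	TPS-g	DDLGSAKDE
DXDD	TPS-c	DXDD
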