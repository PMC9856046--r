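class_id	species	n_crps	size_min	size_max	subgroups	pattern
PCP-A/DEFL/LCR	A.thaliana	19	76	90	CRP0000,CRP0260,CRP0520,CRP0560,CRP0570,CRP0580,CRP0650,CRP0700,CRP0710,CRP0960	CX(5-12)CX(4-8)CXXXCX(9-16)CX(3-14)CXCX(0-5)C
PCP-A/DEFL/LCR	A.lyrata	21	53	96	CRP0000,CRP0260,CRP0520,CRP0560,CRP0570,CRP0580,CRP0650,CRP0700,CRP0710,CRP0960	CX(7-16)CX(4-8)CXXXCX(9-16)CX(4-13)CXC(1-8)C
PCP-A/DEFL/LCR	B.oleracea	32	52	209	CRP0000,CRP0260,CRP0520,CRP0560,CRP0570,CRP0580,CRP0650,CRP0700,CRP0710,CRP0960	CX(3-21)CX(4-11)CXXXCX(9-15)CX(4-12)CXCX(1-6)C
PCP-B	A.thaliana	4	74	82	CRP5460,CRP5500,CRP5515	CXXXXCX(7-8)CXCCX(6-8)CX(6)CXXXC
PCP-B	A.lyrata	2	74	77	CRP5460,CRP5500,CRP5515	CXXXXCX(7-8)CXCCX(6-8)CX(6)CXXXC
PCP-B	B.oleracea	2	66	134	CRP5460,CRP5500,CRP5515	CX(4-10)CX(8)CXCCX(6-9)CX(6)CXXXC
SCRL	A.thaliana	10	87	98	CRP0830	CX(9)CX(7)CX(13-19)CXCX(11-15)CXCX(3-7)C
SCRL	A.lyrata	13	79	105	CRP0830	CX(9-10)CX(7-10)CX(13-19)CXCX(10-16)CXCX(3-7)C
SCRL	B.oleracea	11	73	108	CRP0830	CX(9-10)CX(7-8)CX(13-23)CXCX(11-27)CXCX(3-7)C
nsLTP	A.thaliana	10	91	180	CRP3860,CRP4000,CRP4380,CRP4670,CRP4820,CRP4900	CX(6-9)CX(13-16)CCX(8-19)CXCX(12-25)CX(6-15)C
nsLTP	A.lyrata	7	93	119	CRP3860,CRP4000,CRP4380,CRP4670,CRP4820,CRP4900	CX(6-9)CX(12-16)CCX(8-19)CXCX(17-24)CX(6-15)C
nsLTP	B.oleracea	20	90	265	CRP3860,CRP4000,CRP4380,CRP4670,CRP4820,CRP4900	CX(6-9)CX(13-16)CCX(8-19)CXCX(12-25)CX(6-13)C
GASA	A.thaliana	2	89	94	CRP2700	CXXXCXXXCX(8)CXXXCXXCCXXCX(1-2)CX(11)CXCX(12)C
GASA	A.lyrata	2	89	94	CRP2700	CXXXCXXXCX(8)CXXXCXXCCXXCX(1-2)CX(11)CXCX(12)C
GASA	B.oleracea	2	89	91	CRP2700	CXXXCXXXCX(8)CXXXCXXCCXXCXXCX(11)CXCX(12)C
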