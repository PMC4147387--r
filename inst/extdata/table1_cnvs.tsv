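case	type	band	chrom	start	end	group
case1	Del	11q13.3	11	70077400	70614279	1
case2	Del	6q26	6	162565963	162748669	1
case3	Del	2q21.3	2	135591912	135966218	3
case3	Dup	Xp22.31	X	6442757	8115638	3
case4	Dup	Xp22.31	X	6404592	6907093	2
case5	Dup	10q26.3	10	134492316	134941539	4
case6	Dup	10q26.3	10	134543728	134955025	4
case7	Dup	6p22.3	6	17977030	18137572	1
case8	Dup	10q26.2	10	128750641	129507857	4
case9	Dup	13q12.12	13	24060479	24236403	2
case10	Del	21q21.2	21	23370733	23780822	2
case11	Dup	3q27.1	3	184311092	184784473	4
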