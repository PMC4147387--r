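id	sex	age	group	cgg1	cgg2
case1	M	12	1	64	NA
case2	M	15	1	58	NA
case3	M	5	3	81	NA
case4	M	9	2	66	NA
case5	F	69	4	80	20
case6	F	35	4	106	29
case7	M	14	1	192	NA
case8	M	7	4	99	NA
case9	M	6	2	80	NA
case10	M	6	2	56	NA
case11	F	31	4	102	29
NC01	F	NA	1	NA	NA
NC02	M	NA	1	NA	NA
NC03	M	NA	1	NA	NA
NC04	M	NA	1	NA	NA
NC05	M	NA	1	NA	NA
NC06	M	NA	1	NA	NA
NC07	M	NA	1	NA	NA
NC08	M	NA	1	NA	NA
NC09	M	NA	1	NA	NA
NC10	M	NA	1	NA	NA
NC11	M	NA	1	NA	NA
NC12	M	NA	1	NA	NA
NC13	M	NA	1	NA	NA
NC14	M	NA	1	NA	NA
NC15	M	NA	1	NA	NA
NC16	M	NA	1	NA	NA
NC17	M	NA	2	NA	NA
NC18	M	NA	2	NA	NA
NC19	M	NA	2	NA	NA
NC20	M	NA	2	NA	NA
NC21	M	NA	2	NA	NA
NC22	M	NA	2	NA	NA
NC23	M	NA	2	NA	NA
NC24	M	NA	2	NA	NA
NC25	M	NA	2	NA	NA
NC26	M	NA	2	NA	NA
NC27	M	NA	2	NA	NA
NC28	M	NA	2	NA	NA
NC29	M	NA	2	NA	NA
NC30	M	NA	2	NA	NA
NC31	M	NA	2	NA	NA
NC32	M	NA	2	NA	NA
NC33	M	NA	2	NA	NA
NC34	M	NA	3	NA	NA
NC35	M	NA	3	NA	NA
NC36	M	NA	3	NA	NA
NC37	M	NA	3	NA	NA
NC38	M	NA	3	NA	NA
NC39	M	NA	3	NA	NA
NC40	M	NA	3	NA	NA
NC41	M	NA	3	NA	NA
NC42	M	NA	4	NA	NA
NC43	M	NA	4	NA	NA
NC44	M	NA	4	NA	NA
NC45	M	NA	4	NA	NA
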