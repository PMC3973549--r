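chrom	members	positions
2	miR-200b, miR-200a, miR-429	48455071-48453091
2	miR-30e, miR-30c	17435650-17432816
3	miR-95, miR-218	103550531-103550551
3	miR-328, miR-138	9201088-9201162
4	miR-29b, miR-29a	85327107-85326792
4	miR-183, miR-96	84472003-84471849
5	miR-153-2, miR-101	95527968-95527988
5	miR-205, miR-16, miR-15b	15685339-15685252
6	miR-141, miR-200c	34423490-34423144
7	miR-492-2, miR-708	54764367-54764389
7	miR-492-2, miR-24, miR-27a, miR-23a	44930206-44929889
7	miR-100, miR-125b	29500017-29500052
7	miR-34c, miR-34b	20101717-20101221
7	miR-34b, miR-7-2	2932730-2932799
8	miR-133a, miR-1	39912260-39912288
8	miR-130b, miR-301b	3383110-3382875
10	miR-99b, let-7e, miR-125a	21370890-21371640
11	miR-497, miR-195	50049193-50048962
11	miR-212, miR-132	45640251-45639901
11	miR-144, miR-451	42750581-42750479
12	miR-194, miR-192	25044429-25044298
13	miR-106b, miR-93, miR-25	8034691-8034329
13	miR-193b, miR-365-2	30682640-30682716
14	miR-143, miR-145	28434698-28433339
16	miR-191, let-7g	35442186-35442267
17	miR-92a, miR-19b, miR-20a, miR-19a, miR-18a, miR-17	61793120-61792474
17	miR-16-2, miR-15a	21138923-21138839
18	miR-10b, miR-128-2	19492393-19492419
20	miR-582, miR-30c-2	62697786-62697808
23	miR-342, let-7f, let-7d	54150817-54148904
23	miR-204b-2, miR-7-3	6798843-6798880
23	miR-23b, miR-27b, miR-24-2	2317924-2317244
24	miR-656, miR-541, miR-496, miR-412, miR-410, miR-409, miR-377	42937011-42930226
	miR-369, miR-154
24	miR-485, miR-134, miR-382, miR-487a, miR-655, miR-544-2, miR-889	42925986-42911169
	miR-539, miR-487b, miR-381, miR-1185, miR-376a, miR-376b, miR-376c
24	miR-495, miR-543, miR-1193, miR-494, miR-329, miR-758, miR-323	42906084-42894709
	miR-1197, miR-380, miR-299, miR-411, miR-379
24	miR-136, miR-432, miR-127, miR-433, miR-431	42748685-42745108
25	miR-181b, miR-181a	28673901-28672731
25	miR-126, miR-219-2	31667420-31667458
26	miR-99a-2, miR-125b-2, let-7c	15508980-15509792
28	let-7a, let-7a-2	42016391-42016461
28	miR-33a, miR-135a-2	22270420-22270497
30	miR-653, miR-181a-2	26398982-26399027
30	miR-664, miR-194-2, miR-215	10337974-10337730
X	miR-424, miR-503	106954949-106954687
X	miR-542, miR-451a, miR-450a, miR-450b	106949741-106948733
X	miR-106a, miR-18b, miR-20b, miR-19b-2, miR-92a-2, miR-363	106692701-106691957
X	miR-374a, miR-545	55500596-55500517
X	miR-374b, miR-421	55435984-55435897
X	miR-502, miR-660, miR-500-2, miR-501, miR-362, miR-500	40077407-40073367
X	miR-188, miR-532	40068847-40068549
X	miR-222, miR-221	37091426-37090756
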