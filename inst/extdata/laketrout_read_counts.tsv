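sample	unblocked	blocker1	blocker2	blocker3	blocker4	blocker5	blocker6	blocker7	blocker8
CA14	1	2	15563	4	2	0	3063	1	0
HP15	891	31764	27026	28104	31264	26392	25667	32604	24249
HP3	715	17312	16679	16338	15124	16742	16468	16457	15026
HP5	22915	28638	33531	32896	32817	35572	30021	33338	32155
M1	17786	33462	32911	27914	29213	27962	34345	34337	32637
M4	10060	32023	32609	28101	29926	31023	31073	32294	31569
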