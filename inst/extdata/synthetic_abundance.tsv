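sample_id	F1	F2	F3	F4	F5	F6	F7	F8
S1	0.12503213021573	0.12487587625524	0.129094502137933	0.108517028781298	0.127953507867374	0.127330403824947	0.124875876249482	0.132320674667996
S2	0.141171058855446	0.1302232290879	0.122216660919518	0.132169811945567	0.109383805932274	0.119244874261777	0.130223229101125	0.115367329896392
S3	0.123529960363014	0.119591625449823	0.114278660690258	0.116814492672108	0.128801325751839	0.148543678894742	0.11959162547127	0.128848630706947
S4	0.140295536084694	0.101987336870922	0.108512525337041	0.123136262593062	0.137846486448899	0.136310665345106	0.10198733691191	0.149923850408366
S5	0.135142315840267	0.123251874205737	0.139828987174179	0.110550453887485	0.112930051406551	0.13379110389148	0.123251874144661	0.121253339449639
S6	0.140479609972588	0.172100348612954	0.143558868048267	0.0931892094543436	0.0937835621628758	0.153230773190236	0.110273251343455	0.0933843772152813
S7	0.14997250686253	0.168340568538688	0.147342266383608	0.111933976535172	0.0831598710224479	0.14116563985023	0.108179631686856	0.0899055391204685
S8	0.154885500465697	0.165182242872593	0.150165188649835	0.0959224562361563	0.089741991233656	0.148532974270485	0.10133582886923	0.094233817402348
S9	0.131553295478718	0.161950161334711	0.154622666153033	0.102903368739319	0.104952376107647	0.142874757397406	0.10019848531701	0.100944889472157
S10	0.14233108439403	0.167310980113087	0.161880399908771	0.105691402734502	0.0883954185073175	0.142597120415634	0.105309163127746	0.0864844307989135
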