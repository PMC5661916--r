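category	F0_unique	F3_unique	R0_unique	R3_unique	F0_total	F3_total	R0_total	R3_total
miRNA	67373	57249	59960	58772	2386352	1638016	2635873	2302177
rRNA	56395	80912	81039	98210	729453	1613788	1453854	2451555
repeat	412	345	447	376	957	799	1019	774
snRNA	4811	4600	4096	4259	12452	12260	12838	13164
snoRNA	2152	2197	2584	2396	4567	4583	5840	5522
srpRNA	0	2	0	0	0	2	0	0
tRNA	9007	13069	13810	15819	214125	17084377	467304	696897
unann	12602337	10044731	10917735	9907437	22010746	17084337	21461967	18702763
clean_reads	12742487	10203105	11079671	10087269	25358652	20755724	26038695	24172852
raw_reads	NA	NA	NA	NA	25556975	20959989	26243698	24392550
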