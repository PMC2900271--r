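gene_symbol	total_reads	pct_all	cumulative_pct
CKM	236942	6.9	6.9
MYL1	203634	5.9	12.8
ACTA1	147884	4.3	17.1
TNNC2	147779	4.3	21.4
ALDOA	118636	3.4	24.8
TTN	116385	3.4	28.2
MYLPF	97094	2.8	31.0
MYH1	91271	2.7	33.7
TPM2	73395	2.1	35.8
ATP2A1	59889	1.7	37.6
RPLP1P4	55290	1.6	39.2
ENO3	40827	1.2	40.4
LOC440359	36681	1.1	41.4
ATP5O	34234	1.0	42.4
MYOZ1	32638	0.9	43.4
PYGM	31710	0.9	44.3
TPM1	30823	0.9	45.2
MYBPC2	28386	0.8	46.0
TNNT3	27469	0.8	46.8
CKMT2	27394	0.8	47.6
TNNI2	25005	0.7	48.3
PGK1	24378	0.7	49.0
RPL30	23575	0.7	49.7
NDUFAB1	22285	0.6	50.4
SLC25A4	21881	0.6	51.0
ACTN3	21097	0.6	51.6
PGAM2	21059	0.6	52.2
RPS13	19063	0.6	52.8
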