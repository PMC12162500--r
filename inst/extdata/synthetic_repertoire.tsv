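cell_id	locus	junction_aa
cell0000001	IGH	TYNFYAIVGDQLNHMQKCFI
cell0000002	IGH	WDCMWWEAVFDGSWHEVW
cell0000003	IGH	GWWCRNLNIDDF
cell0000004	IGH	MVLPAVNENAPTHKM
cell0000005	IGH	MNGWLYSA
cell0000006	IGH	ACFSCLRM
cell0000007	IGH	EQWYMWAHPP
cell0000008	IGH	RSWLIWMTC
cell0000009	IGH	VSNAMWIWSYDYV
cell0000010	IGH	CASFSDPHHFCDG
cell0000011	IGH	AIMMKGTVQQWSYMTEQF
cell0000012	IGH	TWCEGMFGEDWCDEAWDA
cell0000013	IGH	HCHNQNEQV
cell0000014	IGH	WKCKGQQYSLDNPPRAQI
cell0000015	IGH	WKTWPFSTSDM
cell0000016	IGH	WPRGKSLPQHYMWQ
cell0000017	IGH	QGYPQVVCCHKNT
cell0000018	IGH	MYPQFRKRPS
cell0000019	IGH	HHVEQDWDLQRY
cell0000020	IGH	NIRPDREPKAHWYYFYRQI
cell0000021	IGH	PDEVTTETDTESNWC
cell0000022	IGH	NPYVFEKVH
cell0000023	IGH	KLETTHFTACHNVF
cell0000024	IGH	CFRNGETTFY
cell0000025	IGH	IHCPEITYGDIY
cell0000026	IGH	VSAMHPAGV
cell0000027	IGH	IHTNVSMCKMDPFHGAYNQQ
cell0000028	IGH	WMFLNAGC
cell0000029	IGH	GHPEGRPMI
cell0000030	IGH	FTPCESDYGQKAYGPVY
cell0000031	IGH	NTPDMLQWPIMFV
cell0000032	IGH	KKVHSFGDYGPEPE
cell0000033	IGH	IGNYPRGRVRQSLCHEQYH
cell0000034	IGH	YAEEDGRRAIL
cell0000035	IGH	WLYAAYCDDHHAGFQ
cell0000036	IGH	RPLVCNDYNSEQLQQ
cell0000037	IGH	PHTCAQLNFEIGWSN
cell0000038	IGH	PHTWSNQRQLMHAFFCGQVP
cell0000039	IGH	WSNQAHMAYGKQSIPHT
cell0000040	IGH	VMNKHKWSNPHT
cell0000041	IGH	DELVKQPCCWSPHTQK
cell0000042	IGH	WSNMPHTVA
cell0000043	IGH	VFGKQSDYPHTWSN
cell0000044	IGH	QIGKQTETWSNFPHT
cell0000045	IGH	VWSNQVCPHTSKQWDNCQ
cell0000046	IGH	WSNPHTNGKQAKYW
cell0000047	IGH	EKHMCDMGPHTNFEVET
cell0000048	IGH	SHWSNLWMANCDVEYSQQ
cell0000049	IGH	TGKQPHTNWFHFIH
cell0000050	IGH	PPHTGKQYWLKTVKWSN
cell0000051	IGH	HWSPHTPPP
cell0000052	IGH	WEDKVLGELPHTQRH
cell0000053	IGH	HMHWSPHTWHDN
cell0000054	IGH	GKQIGWSN
cell0000055	IGH	WSPHTWGKQG
cell0000056	IGH	GPHTDLWSNESNHPK
cell0000057	IGH	NPIPHTSKN
cell0000058	IGH	WSNKPHTNFFMESP
cell0000059	IGH	EAGKQPWSPHTS
cell0000060	IGH	AQNIHPHTN
cell0000061	IGH	MWSNEYPHTQGKQY
cell0000062	IGH	FPHTLFWSNQ
cell0000063	IGH	IEWWPHTQ
cell0000064	IGH	GWSNRPHTF
cell0000065	IGH	ISPHTNQD
cell0000066	IGH	AWQWSPHTQ
cell0000067	IGH	QYAQQLWWSNPHTGKQNCFF
cell0000068	IGH	AQYGCKHWSNVFGPHT
cell0000069	IGH	SNWPHTVWSN
cell0000070	IGH	DTPHTNNAWGKQCYMY
cell0000071	IGH	LGCPHTSNW
cell0000072	IGH	MTPGKQPHTLEDCY
cell0000073	IGH	AGRQGYCYDYL
cell0000074	IGH	YTMDLWIYDYDLTMCE
cell0000075	IGH	FCKKYDYWEAEPPLRFDLAP
cell0000076	IGH	KSFFDLPGWVDPKH
cell0000077	IGH	TIDLYDYFDLLSKGF
cell0000078	IGH	FDLCFKYDYGAYTDD
cell0000079	IGH	NHQIPTYDYDTKCDLWG
cell0000080	IGH	DMDYDYLMQMKS
cell0000081	IGH	EGDHNMYDYLC
cell0000082	IGH	KQQYDYLWDCDLWRMCTQSQ
cell0000083	IGH	TYDYDLWNS
cell0000084	IGH	FDLWYDYC
cell0000085	IGH	NMYNPYDYDFDLGPVIFR
cell0000086	IGH	DLWQYMWYDYLMWP
cell0000087	IGH	EGVSKDYDYFDLW
cell0000088	IGH	DHYDYYACGSDLWIH
cell0000089	IGH	HWELFDYDYW
cell0000090	IGH	FDYDYLWHP
cell0000091	IGH	YDLYDYLNVRCAFDV
cell0000092	IGH	GDLWSDYDYIAG
cell0000093	IGH	CACAHDLWKPTAQYDYFDL
cell0000094	IGH	DLWFLFDL
cell0000095	IGH	ERNPLDLWYDYPFDLLTCR
cell0000096	IGH	ILKPGIMMEFDYDYFFQDLW
cell0000097	IGH	KPHAFDLWWSDLWFWYDYKL
cell0000098	IGH	RPFDLHRQIHDLYDYMFY
cell0000099	IGH	QVFYDYMDFDLDY
cell0000100	IGH	YDYFDLWCY
cell0000101	IGH	YDYDDLWDWIWLFFDLPQYP
cell0000102	IGH	FDLLWGLM
cell0000103	IGH	LNDDDYDYHTFDLIQ
cell0000104	IGH	WDFDYDYG
cell0000105	IGH	PQHEVYDYDLPRIEAN
cell0000106	IGH	YYTRVCCDYDYFFDLSM
cell0000107	IGH	CTIKYHMAKYQNFDLRYDYD
cell0000108	IGH	YDYTYVDLWNDQYCFDLC
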