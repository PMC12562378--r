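gene	category	note
KFSX001	KFS	synthetic placeholder
KFSX002	KFS	synthetic placeholder
KFSX003	KFS	synthetic placeholder
KFSX004	KFS	synthetic placeholder
KFSX005	KFS	synthetic placeholder
KFSX006	KFS	synthetic placeholder
KFSX007	KFS	synthetic placeholder
KFSX008	KFS	synthetic placeholder
KFSX009	KFS	synthetic placeholder
KFSX010	KFS	synthetic placeholder
KFSX011	KFS	synthetic placeholder
KFSX012	KFS	synthetic placeholder
KFSX013	KFS	synthetic placeholder
KFSX014	KFS	synthetic placeholder
KFSX015	KFS	synthetic placeholder
KFSX016	KFS	synthetic placeholder
KFSX017	KFS	synthetic placeholder
KFSX018	KFS	synthetic placeholder
KFSX019	KFS	synthetic placeholder
TBX6	CS	literature gene
DLL3	CS	literature gene
MESP2	CS	literature gene
JAG1	CS	literature gene
NOTCH2	CS	literature gene
FZD6	CS	literature gene
DACT1	CS	literature gene
DISP2	CS	literature gene
PAX3	CS	literature gene
FBN1	CS	literature gene
COL5A1	CS	literature gene
VANGL1	CS	literature gene
VANGL2	CS	literature gene
SCRIB	CS	literature gene
CELSR1	CS	literature gene
CSX016	CS	synthetic placeholder
CSX017	CS	synthetic placeholder
CSX018	CS	synthetic placeholder
CSX019	CS	synthetic placeholder
CSX020	CS	synthetic placeholder
CSX021	CS	synthetic placeholder
CSX022	CS	synthetic placeholder
CSX023	CS	synthetic placeholder
CSX024	CS	synthetic placeholder
CSDX001	OTHER_CSD	synthetic placeholder
CSDX002	OTHER_CSD	synthetic placeholder
CSDX003	OTHER_CSD	synthetic placeholder
CSDX004	OTHER_CSD	synthetic placeholder
CSDX005	OTHER_CSD	synthetic placeholder
CSDX006	OTHER_CSD	synthetic placeholder
CSDX007	OTHER_CSD	synthetic placeholder
CSDX008	OTHER_CSD	synthetic placeholder
CSDX009	OTHER_CSD	synthetic placeholder
CSDX010	OTHER_CSD	synthetic placeholder
CSDX011	OTHER_CSD	synthetic placeholder
CSDX012	OTHER_CSD	synthetic placeholder
CSDX013	OTHER_CSD	synthetic placeholder
CSDX014	OTHER_CSD	synthetic placeholder
CSDX015	OTHER_CSD	synthetic placeholder
CSDX016	OTHER_CSD	synthetic placeholder
CSDX017	OTHER_CSD	synthetic placeholder
CSDX018	OTHER_CSD	synthetic placeholder
CSDX019	OTHER_CSD	synthetic placeholder
CSDX020	OTHER_CSD	synthetic placeholder
CSDX021	OTHER_CSD	synthetic placeholder
CSDX022	OTHER_CSD	synthetic placeholder
CSDX023	OTHER_CSD	synthetic placeholder
CSDX024	OTHER_CSD	synthetic placeholder
CSDX025	OTHER_CSD	synthetic placeholder
CSDX026	OTHER_CSD	synthetic placeholder
CSDX027	OTHER_CSD	synthetic placeholder
CSDX028	OTHER_CSD	synthetic placeholder
CSDX029	OTHER_CSD	synthetic placeholder
CSDX030	OTHER_CSD	synthetic placeholder
CSDX031	OTHER_CSD	synthetic placeholder
CSDX032	OTHER_CSD	synthetic placeholder
CSDX033	OTHER_CSD	synthetic placeholder
CSDX034	OTHER_CSD	synthetic placeholder
CSDX035	OTHER_CSD	synthetic placeholder
CSDX036	OTHER_CSD	synthetic placeholder
CSDX037	OTHER_CSD	synthetic placeholder
CSDX038	OTHER_CSD	synthetic placeholder
CSDX039	OTHER_CSD	synthetic placeholder
CSDX040	OTHER_CSD	synthetic placeholder
CSDX041	OTHER_CSD	synthetic placeholder
CSDX042	OTHER_CSD	synthetic placeholder
CSDX043	OTHER_CSD	synthetic placeholder
CSDX044	OTHER_CSD	synthetic placeholder
CSDX045	OTHER_CSD	synthetic placeholder
CSDX046	OTHER_CSD	synthetic placeholder
CSDX047	OTHER_CSD	synthetic placeholder
CSDX048	OTHER_CSD	synthetic placeholder
CSDX049	OTHER_CSD	synthetic placeholder
CSDX050	OTHER_CSD	synthetic placeholder
CSDX051	OTHER_CSD	synthetic placeholder
CSDX052	OTHER_CSD	synthetic placeholder
CSDX053	OTHER_CSD	synthetic placeholder
CSDX054	OTHER_CSD	synthetic placeholder
CSDX055	OTHER_CSD	synthetic placeholder
CSDX056	OTHER_CSD	synthetic placeholder
CSDX057	OTHER_CSD	synthetic placeholder
CSDX058	OTHER_CSD	synthetic placeholder
CSDX059	OTHER_CSD	synthetic placeholder
CSDX060	OTHER_CSD	synthetic placeholder
CSDX061	OTHER_CSD	synthetic placeholder
CSDX062	OTHER_CSD	synthetic placeholder
CSDX063	OTHER_CSD	synthetic placeholder
CSDX064	OTHER_CSD	synthetic placeholder
CSDX065	OTHER_CSD	synthetic placeholder
CSDX066	OTHER_CSD	synthetic placeholder
CSDX067	OTHER_CSD	synthetic placeholder
CSDX068	OTHER_CSD	synthetic placeholder
CSDX069	OTHER_CSD	synthetic placeholder
CSDX070	OTHER_CSD	synthetic placeholder
CSDX071	OTHER_CSD	synthetic placeholder
CSDX072	OTHER_CSD	synthetic placeholder
CSDX073	OTHER_CSD	synthetic placeholder
CSDX074	OTHER_CSD	synthetic placeholder
CSDX075	OTHER_CSD	synthetic placeholder
CSDX076	OTHER_CSD	synthetic placeholder
CSDX077	OTHER_CSD	synthetic placeholder
CSDX078	OTHER_CSD	synthetic placeholder
CSDX079	OTHER_CSD	synthetic placeholder
CSDX080	OTHER_CSD	synthetic placeholder
CSDX081	OTHER_CSD	synthetic placeholder
CSDX082	OTHER_CSD	synthetic placeholder
CSDX083	OTHER_CSD	synthetic placeholder
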