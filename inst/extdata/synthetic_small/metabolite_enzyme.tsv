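M0001	E001	1
M0001	E002	2
M0001	E003	2
M0001	E006	1
M0001	E007	4
M0001	E010	1
M0001	E011	1
M0001	E015	1
M0002	E001	4
M0002	E003	1
M0002	E006	3
M0002	E007	3
M0002	E011	1
M0003	E003	1
M0003	E005	1
M0003	E006	4
M0003	E007	1
M0003	E011	1
M0004	E001	1
M0004	E003	2
M0004	E009	1
M0004	E010	1
M0004	E012	1
M0004	E014	1
M0004	E015	1
M0005	E001	4
M0005	E004	2
M0005	E009	2
M0005	E026	1
M0006	E003	3
M0006	E004	3
M0006	E010	1
M0006	E011	4
M0006	E012	2
M0006	E013	3
M0006	E018	1
M0007	E006	1
M0007	E014	6
M0007	E015	1
M0008	E001	1
M0008	E002	1
M0008	E008	2
M0008	E010	1
M0008	E011	1
M0008	E014	2
M0009	E002	1
M0009	E019	1
M0009	E021	6
M0009	E024	2
M0009	E025	4
M0009	E027	2
M0010	E016	3
M0010	E020	4
M0010	E021	2
M0010	E022	2
M0010	E024	4
M0010	E025	1
M0010	E026	1
M0010	E027	2
M0010	E028	1
M0010	E029	2
M0010	E030	1
M0011	E017	3
M0011	E021	2
M0011	E027	2
M0012	E006	2
M0012	E016	1
M0012	E017	2
M0012	E028	1
M0012	E029	2
M0013	E018	2
M0013	E022	2
M0013	E029	2
M0014	E018	3
M0014	E019	3
M0014	E020	3
M0014	E021	4
M0014	E022	3
M0014	E030	3
M0015	E016	3
M0015	E018	1
M0015	E020	2
M0015	E022	1
M0015	E024	1
M0015	E025	2
M0015	E030	1
M0016	E019	2
M0016	E020	1
M0016	E021	1
M0016	E022	2
M0016	E023	2
M0016	E026	1
M0016	E027	1
M0016	E029	2
M0016	E030	2
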