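D001	S001	1
D001	S003	2
D001	S004	2
D001	S008	3
D003	S001	1
D003	S002	2
D003	S010	1
D004	S003	1
D004	S004	2
D004	S007	2
D004	S010	1
D005	S005	3
D005	S009	1
D005	S010	3
D005	S014	1
D006	S004	2
D006	S011	2
D006	S012	5
D006	S013	2
D006	S015	2
D006	S016	2
D006	S018	1
D006	S020	2
D007	S013	1
D007	S014	4
D007	S018	5
D008	S011	1
D008	S013	2
D008	S018	3
D008	S019	2
D009	S011	3
D009	S020	1
D010	S012	2
D010	S013	2
D010	S014	1
D010	S016	4
D010	S020	2
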