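D001	M0001
D002	M0001
D004	M0001
D005	M0001
D001	M0002
D002	M0002
D001	M0003
D003	M0003
D004	M0003
D005	M0003
D008	M0003
D002	M0004
D003	M0004
D004	M0004
D001	M0005
D002	M0005
D003	M0005
D005	M0005
D008	M0005
D003	M0006
D004	M0006
D005	M0006
D001	M0007
D003	M0007
D002	M0008
D003	M0008
D004	M0008
D006	M0009
D007	M0009
D010	M0009
D003	M0010
D006	M0010
D008	M0010
D010	M0010
D006	M0011
D010	M0011
D006	M0012
D008	M0012
D010	M0012
D006	M0013
D007	M0013
D006	M0014
D007	M0014
D008	M0015
D010	M0015
D007	M0016
D008	M0016
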