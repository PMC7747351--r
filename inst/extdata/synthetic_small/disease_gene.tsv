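D001	G002
D001	G004
D001	G005
D001	G007
D001	G008
D001	G010
D001	G011
D001	G013
D001	G017
D001	G019
D001	G020
D002	G001
D002	G002
D002	G004
D002	G008
D002	G009
D002	G015
D002	G027
D003	G003
D003	G010
D003	G012
D003	G014
D003	G018
D003	G019
D003	G035
D004	G001
D004	G005
D004	G007
D004	G012
D004	G014
D004	G017
D004	G018
D004	G020
D004	G032
D005	G002
D005	G003
D005	G006
D005	G009
D005	G010
D005	G012
D005	G013
D005	G018
D006	G023
D006	G028
D006	G030
D006	G035
D006	G036
D006	G040
D007	G024
D007	G025
D007	G027
D007	G031
D007	G033
D007	G034
D007	G036
D007	G037
D007	G038
D007	G040
D008	G024
D008	G025
D008	G026
D008	G028
D008	G029
D008	G037
D008	G040
D009	G024
D009	G028
D009	G030
D009	G031
D009	G035
D009	G037
D009	G038
D010	G003
D010	G021
D010	G022
D010	G023
D010	G028
D010	G029
D010	G032
D010	G033
D010	G035
D010	G038
D010	G039
D010	G040
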