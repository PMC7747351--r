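M0001
M0002
M0003
M0004
M0005
M0006
M0007
M0008
M0009
M0010
M0011
M0012
M0013
M0014
M0015
M0016
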