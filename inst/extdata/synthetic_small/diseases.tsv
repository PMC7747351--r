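D001
D002
D003
D004
D005
D006
D007
D008
D009
D010
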