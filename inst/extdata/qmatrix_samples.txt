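CW01
CW02
CW03
CW04
CW05
CW06
CW07
CW08
CW09
CW10
CW11
CW12
CW13
CW14
CW15
CW16
CW17
CW18
CW19
CW20
CW21
CW22
CW23
CW24
CW25
CW26
CW27
CW28
CW29
CW30
CW31
CW32
CW33
CW34
CW35
CW36
CW37
CW38
CW39
CW40
CW41
CW42
CW43
CW44
CW45
CW46
CW47
CW48
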