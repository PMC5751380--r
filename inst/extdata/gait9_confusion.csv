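class,standing,sitting,walk_forward,turn_left,turn_right,upstairs,downstairs,jog,jump
standing,186,14,0,0,0,0,0,0,0
sitting,6,184,10,0,0,0,0,0,0
walk_forward,4,0,194,0,0,2,0,0,0
turn_left,4,0,6,188,2,0,0,0,0
turn_right,6,4,0,0,190,0,0,0,0
upstairs,0,6,0,0,0,196,0,4,0
downstairs,4,2,0,0,0,0,194,0,0
jog,0,0,0,0,0,4,1,200,0
jump,0,0,6,0,0,4,6,4,180
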