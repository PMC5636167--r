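............
.HH.........
.........V..
.....@...V..
............
...HH.......
............
........HH..
.V..........
.V....V.....
......V.....
............
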