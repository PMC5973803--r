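# Staircase (up-down) coefficients k for terminal response patterns.
# O = no response (step up), X = response (step down); pattern starts at
# the trial before the first response change. k is the maximum-likelihood
# location estimate (in step units, relative to the final stimulus level)
# under a normal tolerance distribution with SD equal to the step size --
# the model the classical small-sample up-down tables were computed for.
# 50% threshold = 10^(log10(final force) + k * mean log10 step).
# Generated by pbspike:::computeUpdownK().
pattern	k
OX	-0.500000
XO	0.500000
OXO	0.841647
OXX	-0.177961
XOO	0.177961
XOX	-0.841647
OXOO	0.299193
OXXO	1.000000
OXOX	-0.500000
OXXX	0.194366
XOOO	-0.194366
XOXO	0.500000
XOOX	-1.000000
XOXX	-0.299193
OXOOO	-0.157059
OXXOO	0.305483
OXOXO	0.700532
OXXXO	1.288087
OXOOX	-0.878427
OXXOX	-0.305483
OXOXX	0.083538
OXXXX	0.555297
XOOOO	-0.555297
XOXOO	-0.083538
XOOXO	0.305483
XOXXO	0.878427
XOOOX	-1.288087
XOXOX	-0.700532
XOOXX	-0.305483
XOXXX	0.157059
OXOOOO	-0.547046
OXXOOO	-0.295915
OXOXOO	0.021541
OXXXOO	0.500000
OXOOXO	0.372007
OXXOXO	0.831348
OXOXXO	1.168652
OXXXXO	1.603423
OXOOOX	-1.250123
OXXOOX	-0.831348
OXOXOX	-0.500000
OXXXOX	-0.043148
OXOOXX	-0.168652
OXXOXX	0.295915
OXOXXX	0.610788
OXXXXX	0.893064
XOOOOO	-0.893064
XOXOOO	-0.610788
XOOXOO	-0.295915
XOXXOO	0.168652
XOOOXO	0.043148
XOXOXO	0.500000
XOOXXO	0.831348
XOXXXO	1.250123
XOOOOX	-1.603423
XOXOOX	-1.168652
XOOXOX	-0.831348
XOXXOX	-0.372007
XOOOXX	-0.500000
XOXOXX	-0.021541
XOOXXX	0.295915
XOXXXX	0.547046
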