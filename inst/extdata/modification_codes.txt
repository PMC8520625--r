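# Default one-letter codes for modified nucleotides, mapped to the parent
# base they derive from.  The set covers common single-character short codes
# for abundant RNA modifications; users with other conventions can supply
# their own two-column table (code, parent) via the `table` argument or the
# command-line flag.
# code  parent
P U
D U
I A
7 G
K G
L G
M C
B C
H A
J U
Z C
# ambiguity code: unknown base, restored verbatim on output
N A
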