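# Refined U6 haplogroup tree: name <TAB> parent <TAB> defining variant tokens.
# Coordinates are rCRS positions; "!" marks a back-mutation, "d" a deletion,
# ".N" an insertion index. The root motif is the branch separating U6 from the
# basal macro-haplogroup U. Clades whose internal subdivision is not further
# diagnosable are attached to their nearest diagnosable ancestor; U6a2'3 joins
# the 16189-sharing U6a2/U6a3 branches, and the recurrent 16311 appears
# independently on the U6b and U6d sister branches.
U6	-	3348 16172
U6a'b'd	U6	16219
U6a	U6a'b'd	16278
U6a1a1	U6a	16189 16239
U6a1a1a2	U6a1a1	13071
U6a1b	U6a	16235
U6a1b1b	U6a1b	2158 10336 14034 16145
U6a2'3	U6a	16189
U6a2a3	U6a2'3	4936 9100 9128 10172 16295 5894C 9335A
U6a2a3a	U6a2a3	15626!
U6a2b	U6a2'3	15383 16354
U6a2b1	U6a2b	15314 16184
U6a2c	U6a2'3	195
U6a3a1b	U6a2'3	8598
U6a3b1a	U6a2'3	16311
U6a3c	U6a2'3	146 291.1A 960d 1809 5554A 6182 11272 15380
U6a3e	U6a2'3	185 3337 4021 8705 12097 13569 13928 16362 16399
U6a3f	U6a2'3	150 185 310 8763
U6a3g	U6a2'3	150 3826
U6a8	U6a2'3	143 8282 10172 11539 750!
U6a5a1	U6a	11191
U6a5b	U6a	3714 16184 16234
U6a6a	U6a	16079
U6a6a1	U6a6a	9031
U6a7a1	U6a	5120
U6a7a1a	U6a7a1	2672 11929
U6a7a1b	U6a7a1	150
U6a7a1c	U6a7a1	152!
U6a7a2a	U6a	14034
U6a7a2a1	U6a7a2a	11941
U6a7b1	U6a	12950C
U6a7b1a	U6a7b1	455.1T 960.1C 11818C 12940 13879
U6b	U6a'b'd	16311
U6b1	U6b	9738 15431
U6b1a	U6b1	2352 16163
U6b1a1	U6b1a	7700
U6b1a2	U6b1a	6734
U6b1a3	U6b1a	15697 16092
U6b2	U6b	4062 12535 13637 15355
U6b3	U6b	16278
U6b3a	U6b3	235
U6b4	U6b	5442 16051
U6b5	U6b	5773 8951 14053 16111 16362
U6d	U6a'b'd	16311
U6d1	U6d	16261
U6d3	U6d	16174
U6c	U6	16169 16189
U6c1	U6c	16129
U6c1a	U6c1	12406 16111
U6c1b	U6c1	16086
U6c1c	U6c1	5964 12092A 15617
U6c2	U6c	194
U6c2a	U6c2	3866
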