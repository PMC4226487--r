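mspms 12 3 -t 8 -r 6 10000 -seeds 7 8 9
7 8 9

//
segsites: 21
positions: 0.199 0.260 0.269 0.300 0.304 0.408 0.422 0.453 0.491 0.514 0.554 0.562 0.592 0.690 0.709 0.745 0.772 0.858 0.929 0.954 0.961 
100000000111000001110
011000110000101110000
100000000101000111111
000011000111010001111
011000110000101110000
100000000101000111000
010100111000100110000
100000000101000111111
010000110000100110000
011000110000100001110
100000000101000111111
000011000111010001111

//
segsites: 43
positions: 0.069 0.108 0.143 0.201 0.208 0.225 0.292 0.296 0.310 0.321 0.323 0.345 0.347 0.391 0.415 0.449 0.450 0.476 0.482 0.486 0.495 0.509 0.558 0.586 0.609 0.617 0.622 0.637 0.647 0.692 0.735 0.828 0.840 0.843 0.881 0.912 0.913 0.934 0.965 0.970 0.981 0.992 0.997 
0001001000100100100101000110010100000100000
1010010001010001010010000001001000101001100
1010010001010001010010000001001010111000100
1110010110001011001010110000101001000000001
1110010010001011001010110000101001000000001
1010010001010001010010000001001010111000100
1110110010001001001010110000001001000010001
1110010010001011001010110000001001000000001
1110010010001011001010001001001000101001100
1010010001010001010010000001001010111000100
1110010010001011001010110000001000101001110
1110010010001011001010110000101001000000001

//
segsites: 19
positions: 0.129 0.130 0.143 0.208 0.279 0.298 0.363 0.535 0.600 0.611 0.695 0.698 0.798 0.933 0.955 0.965 0.987 0.997 0.999 
0111010000000110000
0000100000010001011
0000101000011001011
0000000000010001001
1000010011100110000
0000100100010001101
0000100000010001011
0000010000000110000
1000010011100110000
1000010011100110000
0000000000010001001
0000100100010001101
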