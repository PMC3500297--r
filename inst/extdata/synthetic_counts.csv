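"segment","stratum","year","count"
"S1_seg1","S1",1957,4
"S1_seg2","S1",1957,2
"S1_seg3","S1",1957,2
"S1_seg4","S1",1957,2
"S1_seg1","S1",1958,7
"S1_seg2","S1",1958,0
"S1_seg3","S1",1958,3
"S1_seg4","S1",1958,0
"S1_seg1","S1",1959,10
"S1_seg2","S1",1959,4
"S1_seg3","S1",1959,3
"S1_seg4","S1",1959,4
"S1_seg1","S1",1960,1
"S1_seg2","S1",1960,1
"S1_seg3","S1",1960,6
"S1_seg4","S1",1960,3
"S1_seg1","S1",1961,2
"S1_seg2","S1",1961,9
"S1_seg3","S1",1961,2
"S1_seg4","S1",1961,8
"S1_seg1","S1",1962,0
"S1_seg2","S1",1962,4
"S1_seg3","S1",1962,9
"S1_seg4","S1",1962,5
"S1_seg1","S1",1963,6
"S1_seg2","S1",1963,3
"S1_seg3","S1",1963,0
"S1_seg4","S1",1963,0
"S1_seg1","S1",1964,0
"S1_seg2","S1",1964,19
"S1_seg3","S1",1964,18
"S1_seg4","S1",1964,8
"S2_seg1","S2",1957,1
"S2_seg2","S2",1957,0
"S2_seg3","S2",1957,1
"S2_seg4","S2",1957,0
"S2_seg1","S2",1958,7
"S2_seg2","S2",1958,0
"S2_seg3","S2",1958,0
"S2_seg4","S2",1958,1
"S2_seg1","S2",1959,1
"S2_seg2","S2",1959,8
"S2_seg3","S2",1959,1
"S2_seg4","S2",1959,5
"S2_seg1","S2",1960,0
"S2_seg2","S2",1960,0
"S2_seg3","S2",1960,1
"S2_seg4","S2",1960,0
"S2_seg1","S2",1961,0
"S2_seg2","S2",1961,1
"S2_seg3","S2",1961,1
"S2_seg4","S2",1961,0
"S2_seg1","S2",1962,0
"S2_seg2","S2",1962,1
"S2_seg3","S2",1962,1
"S2_seg4","S2",1962,0
"S2_seg1","S2",1963,0
"S2_seg2","S2",1963,0
"S2_seg3","S2",1963,0
"S2_seg4","S2",1963,1
"S2_seg1","S2",1964,0
"S2_seg2","S2",1964,0
"S2_seg3","S2",1964,0
"S2_seg4","S2",1964,1
"S3_seg1","S3",1957,2
"S3_seg2","S3",1957,0
"S3_seg3","S3",1957,3
"S3_seg4","S3",1957,2
"S3_seg1","S3",1958,2
"S3_seg2","S3",1958,1
"S3_seg3","S3",1958,0
"S3_seg4","S3",1958,1
"S3_seg1","S3",1959,3
"S3_seg2","S3",1959,2
"S3_seg3","S3",1959,0
"S3_seg4","S3",1959,1
"S3_seg1","S3",1960,11
"S3_seg2","S3",1960,7
"S3_seg3","S3",1960,7
"S3_seg4","S3",1960,15
"S3_seg1","S3",1961,3
"S3_seg2","S3",1961,1
"S3_seg3","S3",1961,5
"S3_seg4","S3",1961,4
"S3_seg1","S3",1962,2
"S3_seg2","S3",1962,0
"S3_seg3","S3",1962,4
"S3_seg4","S3",1962,4
"S3_seg1","S3",1963,4
"S3_seg2","S3",1963,2
"S3_seg3","S3",1963,7
"S3_seg4","S3",1963,1
"S3_seg1","S3",1964,2
"S3_seg2","S3",1964,3
"S3_seg3","S3",1964,1
"S3_seg4","S3",1964,0
"S4_seg1","S4",1957,0
"S4_seg2","S4",1957,1
"S4_seg3","S4",1957,0
"S4_seg4","S4",1957,0
"S4_seg1","S4",1958,0
"S4_seg2","S4",1958,0
"S4_seg3","S4",1958,1
"S4_seg4","S4",1958,1
"S4_seg1","S4",1959,4
"S4_seg2","S4",1959,0
"S4_seg3","S4",1959,0
"S4_seg4","S4",1959,1
"S4_seg1","S4",1960,0
"S4_seg2","S4",1960,4
"S4_seg3","S4",1960,1
"S4_seg4","S4",1960,2
"S4_seg1","S4",1961,0
"S4_seg2","S4",1961,0
"S4_seg3","S4",1961,0
"S4_seg4","S4",1961,0
"S4_seg1","S4",1962,2
"S4_seg2","S4",1962,1
"S4_seg3","S4",1962,2
"S4_seg4","S4",1962,2
"S4_seg1","S4",1963,1
"S4_seg2","S4",1963,2
"S4_seg3","S4",1963,0
"S4_seg4","S4",1963,5
"S4_seg1","S4",1964,2
"S4_seg2","S4",1964,0
"S4_seg3","S4",1964,0
"S4_seg4","S4",1964,1
"S5_seg1","S5",1957,3
"S5_seg2","S5",1957,2
"S5_seg3","S5",1957,1
"S5_seg4","S5",1957,1
"S5_seg1","S5",1958,6
"S5_seg2","S5",1958,1
"S5_seg3","S5",1958,0
"S5_seg4","S5",1958,5
"S5_seg1","S5",1959,3
"S5_seg2","S5",1959,3
"S5_seg3","S5",1959,0
"S5_seg4","S5",1959,3
"S5_seg1","S5",1960,5
"S5_seg2","S5",1960,0
"S5_seg3","S5",1960,3
"S5_seg4","S5",1960,0
"S5_seg1","S5",1961,0
"S5_seg2","S5",1961,4
"S5_seg3","S5",1961,7
"S5_seg4","S5",1961,0
"S5_seg1","S5",1962,1
"S5_seg2","S5",1962,0
"S5_seg3","S5",1962,0
"S5_seg4","S5",1962,1
"S5_seg1","S5",1963,1
"S5_seg2","S5",1963,4
"S5_seg3","S5",1963,0
"S5_seg4","S5",1963,0
"S5_seg1","S5",1964,0
"S5_seg2","S5",1964,1
"S5_seg3","S5",1964,0
"S5_seg4","S5",1964,3
"S6_seg1","S6",1957,0
"S6_seg2","S6",1957,0
"S6_seg3","S6",1957,0
"S6_seg4","S6",1957,3
"S6_seg1","S6",1958,0
"S6_seg2","S6",1958,0
"S6_seg3","S6",1958,0
"S6_seg4","S6",1958,1
"S6_seg1","S6",1959,1
"S6_seg2","S6",1959,0
"S6_seg3","S6",1959,1
"S6_seg4","S6",1959,1
"S6_seg1","S6",1960,0
"S6_seg2","S6",1960,0
"S6_seg3","S6",1960,0
"S6_seg4","S6",1960,0
"S6_seg1","S6",1961,0
"S6_seg2","S6",1961,1
"S6_seg3","S6",1961,0
"S6_seg4","S6",1961,1
"S6_seg1","S6",1962,0
"S6_seg2","S6",1962,0
"S6_seg3","S6",1962,3
"S6_seg4","S6",1962,0
"S6_seg1","S6",1963,2
"S6_seg2","S6",1963,3
"S6_seg3","S6",1963,6
"S6_seg4","S6",1963,3
"S6_seg1","S6",1964,1
"S6_seg2","S6",1964,6
"S6_seg3","S6",1964,2
"S6_seg4","S6",1964,3
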