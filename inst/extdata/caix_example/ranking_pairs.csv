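compound_id,dist_x,iqspr_rank,ifd_score,docking_rank,final_rank
C101,0.044,1,-504.11,6,4
C108,0.044,2,-503.69,7,5
A1279,0.081,3,-495.03,12,8
A0504,0.097,4,-496.64,9,7
C102,0.099,5,-505.78,1,3
A0277,0.100,6,-503.22,8,7
C97,0.110,7,-504.76,4,6
A0337,0.115,8,-493.14,14,11
A0456,0.115,9,-504.90,3,6
C106,0.149,11,-505.40,2,7
C105,0.340,12,-504.29,5,9
C75,0.429,13,-493.66,13,13
C89,0.982,14,-495.48,11,13
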