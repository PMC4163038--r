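subject_id,group,domain,block,trial_index,stimulus_side,response_side,accuracy,confidence_raw,condition_tag
s01,demo,perception,1,1,left,left,1,2.02188724832032,4
s01,demo,perception,1,2,left,left,1,3.64430818849058,4
s01,demo,perception,1,3,left,left,1,5.65959152990215,3
s01,demo,perception,1,4,right,left,0,3.65615758373483,3
s01,demo,perception,1,5,right,left,0,4.90874297255905,4
s01,demo,memory,1,1,right,left,0,4.38153823011075,1
s01,demo,memory,1,2,left,left,1,4.06567887756876,1
s01,demo,memory,1,3,left,left,1,3.9900795442076,1
s01,demo,memory,1,4,right,right,1,4.82800867668525,1
s01,demo,memory,1,5,right,left,0,2.84859242176239,1
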