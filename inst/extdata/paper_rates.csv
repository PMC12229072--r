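label,events,denominator,ci_method
error_post,5,18762,clopper_pearson
error_pre,1,18767,clopper_pearson
near_miss_post,30,18762,clopper_pearson
near_miss_pre,9,18767,clopper_pearson
flagged_face_post,0,18762,wilson
flagged_laterality_post,7,18762,wilson
flagged_iol_post,28,9713,wilson
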