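aliquot_id,chase_time,time_unit,gene_role,replicate,ct
r1_t0,0,h,study,1,22
r1_t0,0,h,study,2,22
r1_t0,0,h,study,3,22
r1_t0,0,h,control,1,16
r1_t0,0,h,control,2,16
r1_t0,0,h,control,3,16
r1_t6,6,h,study,1,22
r1_t6,6,h,study,2,22
r1_t6,6,h,study,3,22
r1_t6,6,h,control,1,15
r1_t6,6,h,control,2,15
r1_t6,6,h,control,3,15
r1_t12,12,h,study,1,22
r1_t12,12,h,study,2,22
r1_t12,12,h,study,3,22
r1_t12,12,h,control,1,14
r1_t12,12,h,control,2,14
r1_t12,12,h,control,3,14
r1_t18,18,h,study,1,22
r1_t18,18,h,study,2,22
r1_t18,18,h,study,3,22
r1_t18,18,h,control,1,13
r1_t18,18,h,control,2,13
r1_t18,18,h,control,3,13
r1_t24,24,h,study,1,22
r1_t24,24,h,study,2,22
r1_t24,24,h,study,3,22
r1_t24,24,h,control,1,12
r1_t24,24,h,control,2,12
r1_t24,24,h,control,3,12
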