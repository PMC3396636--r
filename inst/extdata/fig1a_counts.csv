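aliquot_id,chase_time,time_unit,count,true_count
r1_t0,0,h,10000,10000
r1_t6,6,h,20000,20000
r1_t12,12,h,40000,40000
r1_t18,18,h,79999.99999999999,79999.99999999999
r1_t24,24,h,159999.99999999997,159999.99999999997
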