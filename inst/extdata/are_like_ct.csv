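aliquot_id,chase_time,time_unit,gene_role,replicate,ct
r1_t0,0,min,study,1,21.94229219836444
r1_t0,0,min,study,2,21.94229219836444
r1_t0,0,min,study,3,21.94229219836444
r1_t0,0,min,control,1,15.942292198364441
r1_t0,0,min,control,2,15.942292198364441
r1_t0,0,min,control,3,15.942292198364441
r1_t5,5,min,study,1,22.186107660274676
r1_t5,5,min,study,2,22.186107660274676
r1_t5,5,min,study,3,22.186107660274676
r1_t5,5,min,control,1,15.942292198364441
r1_t5,5,min,control,2,15.942292198364441
r1_t5,5,min,control,3,15.942292198364441
r1_t10,10,min,study,1,22.42992312218491
r1_t10,10,min,study,2,22.42992312218491
r1_t10,10,min,study,3,22.42992312218491
r1_t10,10,min,control,1,15.942292198364441
r1_t10,10,min,control,2,15.942292198364441
r1_t10,10,min,control,3,15.942292198364441
r1_t15,15,min,study,1,22.673738584095144
r1_t15,15,min,study,2,22.673738584095144
r1_t15,15,min,study,3,22.673738584095144
r1_t15,15,min,control,1,15.942292198364441
r1_t15,15,min,control,2,15.942292198364441
r1_t15,15,min,control,3,15.942292198364441
r1_t20,20,min,study,1,22.91755404600538
r1_t20,20,min,study,2,22.91755404600538
r1_t20,20,min,study,3,22.91755404600538
r1_t20,20,min,control,1,15.942292198364441
r1_t20,20,min,control,2,15.942292198364441
r1_t20,20,min,control,3,15.942292198364441
r1_t25,25,min,study,1,23.161369507915616
r1_t25,25,min,study,2,23.161369507915616
r1_t25,25,min,study,3,23.161369507915616
r1_t25,25,min,control,1,15.942292198364441
r1_t25,25,min,control,2,15.942292198364441
r1_t25,25,min,control,3,15.942292198364441
r1_t30,30,min,study,1,23.40518496982585
r1_t30,30,min,study,2,23.40518496982585
r1_t30,30,min,study,3,23.40518496982585
r1_t30,30,min,control,1,15.942292198364441
r1_t30,30,min,control,2,15.942292198364441
r1_t30,30,min,control,3,15.942292198364441
r1_t35,35,min,study,1,23.649000431736084
r1_t35,35,min,study,2,23.649000431736084
r1_t35,35,min,study,3,23.649000431736084
r1_t35,35,min,control,1,15.942292198364441
r1_t35,35,min,control,2,15.942292198364441
r1_t35,35,min,control,3,15.942292198364441
r1_t40,40,min,study,1,23.89281589364632
r1_t40,40,min,study,2,23.89281589364632
r1_t40,40,min,study,3,23.89281589364632
r1_t40,40,min,control,1,15.942292198364441
r1_t40,40,min,control,2,15.942292198364441
r1_t40,40,min,control,3,15.942292198364441
r1_t45,45,min,study,1,24.136631355556556
r1_t45,45,min,study,2,24.136631355556556
r1_t45,45,min,study,3,24.136631355556556
r1_t45,45,min,control,1,15.942292198364441
r1_t45,45,min,control,2,15.942292198364441
r1_t45,45,min,control,3,15.942292198364441
r1_t50,50,min,study,1,24.38044681746679
r1_t50,50,min,study,2,24.38044681746679
r1_t50,50,min,study,3,24.38044681746679
r1_t50,50,min,control,1,15.942292198364441
r1_t50,50,min,control,2,15.942292198364441
r1_t50,50,min,control,3,15.942292198364441
r1_t55,55,min,study,1,24.624262279377024
r1_t55,55,min,study,2,24.624262279377024
r1_t55,55,min,study,3,24.624262279377024
r1_t55,55,min,control,1,15.942292198364441
r1_t55,55,min,control,2,15.942292198364441
r1_t55,55,min,control,3,15.942292198364441
r1_t60,60,min,study,1,24.86807774128726
r1_t60,60,min,study,2,24.86807774128726
r1_t60,60,min,study,3,24.86807774128726
r1_t60,60,min,control,1,15.942292198364441
r1_t60,60,min,control,2,15.942292198364441
r1_t60,60,min,control,3,15.942292198364441
r1_t65,65,min,study,1,25.111893203197493
r1_t65,65,min,study,2,25.111893203197493
r1_t65,65,min,study,3,25.111893203197493
r1_t65,65,min,control,1,15.942292198364441
r1_t65,65,min,control,2,15.942292198364441
r1_t65,65,min,control,3,15.942292198364441
r1_t70,70,min,study,1,25.35570866510773
r1_t70,70,min,study,2,25.35570866510773
r1_t70,70,min,study,3,25.35570866510773
r1_t70,70,min,control,1,15.942292198364441
r1_t70,70,min,control,2,15.942292198364441
r1_t70,70,min,control,3,15.942292198364441
r1_t75,75,min,study,1,25.599524127017965
r1_t75,75,min,study,2,25.599524127017965
r1_t75,75,min,study,3,25.599524127017965
r1_t75,75,min,control,1,15.942292198364441
r1_t75,75,min,control,2,15.942292198364441
r1_t75,75,min,control,3,15.942292198364441
r1_t80,80,min,study,1,25.8433395889282
r1_t80,80,min,study,2,25.8433395889282
r1_t80,80,min,study,3,25.8433395889282
r1_t80,80,min,control,1,15.942292198364441
r1_t80,80,min,control,2,15.942292198364441
r1_t80,80,min,control,3,15.942292198364441
r1_t85,85,min,study,1,26.087155050838433
r1_t85,85,min,study,2,26.087155050838433
r1_t85,85,min,study,3,26.087155050838433
r1_t85,85,min,control,1,15.942292198364441
r1_t85,85,min,control,2,15.942292198364441
r1_t85,85,min,control,3,15.942292198364441
r1_t90,90,min,study,1,26.330970512748667
r1_t90,90,min,study,2,26.330970512748667
r1_t90,90,min,study,3,26.330970512748667
r1_t90,90,min,control,1,15.942292198364441
r1_t90,90,min,control,2,15.942292198364441
r1_t90,90,min,control,3,15.942292198364441
r1_t95,95,min,study,1,26.5747859746589
r1_t95,95,min,study,2,26.5747859746589
r1_t95,95,min,study,3,26.5747859746589
r1_t95,95,min,control,1,15.942292198364441
r1_t95,95,min,control,2,15.942292198364441
r1_t95,95,min,control,3,15.942292198364441
r1_t100,100,min,study,1,26.81860143656914
r1_t100,100,min,study,2,26.81860143656914
r1_t100,100,min,study,3,26.81860143656914
r1_t100,100,min,control,1,15.942292198364441
r1_t100,100,min,control,2,15.942292198364441
r1_t100,100,min,control,3,15.942292198364441
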