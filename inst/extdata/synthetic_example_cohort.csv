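id,age_dx,size_mm,grade,nodes_pos,nodes_sampled,er,her2,ki67,detection,therapy,follow_up_years,outcome
P00001,71.8544273893349,19.93101819884032,2,0,8,pos,,neg,symptomatic,endocrine,10,censored
P00002,67.4142281780951,15.18923443509266,,,,pos,neg,neg,symptomatic,none,10,censored
P00003,35.4856908256188,22.61089933570474,3,0,15,pos,,neg,symptomatic,endocrine,10,censored
P00004,66.4220569969621,19.64432229055092,3,1,15,pos,neg,,symptomatic,endocrine,10,censored
P00005,52.7236311533488,28.87126861140132,2,0,11,pos,neg,,symptomatic,endocrine,10,censored
P00006,80.2187632501591,42.22338312771171,3,3,17,neg,,,screen,chemo,10,censored
P00007,64.5512211043388,27.61508461786434,2,1,10,pos,neg,pos,symptomatic,endocrine,10,censored
P00008,40.4554469836876,18.53153161238879,3,0,11,pos,neg,pos,symptomatic,endocrine,10,censored
P00009,59.8813921562396,14.19716885313392,2,0,18,neg,,,screen,chemo,1.01290026555182,bc_death
P00010,51.8610942922533,20.88327310746536,3,2,18,pos,pos,pos,symptomatic,endocrine,10,censored
P00011,31.2781472653151,29.20913096051663,3,0,19,pos,neg,,symptomatic,none,5.90962962079916,bc_death
P00012,58.264369899407,35.49578730016947,,0,6,pos,neg,pos,symptomatic,both,10,censored
P00013,62.4291841022205,29.01267467765138,3,0,6,neg,neg,,symptomatic,chemo,6.50455662724171,bc_death
P00014,57.7341684512794,21.76384631777182,2,0,12,neg,,neg,symptomatic,chemo,10,censored
P00015,77.3432507668622,17.20885068411008,1,0,6,pos,neg,pos,screen,endocrine,10,censored
P00016,56.3803709321655,65.46849411446601,3,0,15,pos,neg,neg,symptomatic,none,10,censored
P00017,64.9184244940989,47.99096168484539,2,,,pos,neg,pos,symptomatic,none,7.89132052389907,bc_death
P00018,58.0261974851601,20.78379944432527,2,2,20,pos,,neg,symptomatic,endocrine,10,censored
P00019,40.6602950487286,4.33761196024716,,0,17,pos,,neg,symptomatic,endocrine,10,censored
P00020,32.304681411013,8.51173272635788,2,0,15,pos,neg,,symptomatic,endocrine,10,censored
P00021,58.853819379583,6.11417429079302,2,0,9,pos,,neg,symptomatic,both,10,censored
P00022,51.052993691992,42.37301066517830,2,,,pos,neg,pos,symptomatic,endocrine,10,censored
P00023,51.5200657583773,32.32009167782962,3,0,13,pos,,pos,symptomatic,endocrine,5.00329800402572,bc_death
P00024,53.993272727821,20.83740218076855,3,0,5,pos,,,symptomatic,endocrine,10,censored
P00025,80.6486788752954,26.29077126272023,3,,,pos,neg,neg,symptomatic,endocrine,5.03628844453803,other_death
P00026,52.8812781278975,21.10427104867995,2,0,5,pos,neg,,screen,none,10,censored
P00027,52.9351166333072,11.39529946027324,3,0,7,pos,neg,pos,symptomatic,chemo,7.31685328026588,bc_death
P00028,67.0565960370004,11.77255258429796,2,0,5,pos,,,symptomatic,none,2.53229747074075,other_death
P00029,46.9605760439299,23.02466287510470,2,0,13,pos,neg,neg,symptomatic,none,10,censored
P00030,81.8847775133327,12.90394791169092,3,1,20,pos,neg,neg,symptomatic,endocrine,10,censored
P00031,53.6219758819789,14.68853307887912,1,1,19,pos,,neg,symptomatic,endocrine,10,censored
P00032,42.0404627663083,14.80754690943286,2,0,9,pos,neg,neg,symptomatic,none,10,censored
P00033,82.6917109743226,13.63446006784216,1,,,pos,,neg,symptomatic,endocrine,10,censored
P00034,49.9379383213818,27.56609485950321,2,0,8,pos,neg,,symptomatic,endocrine,7.7362021883001,bc_death
P00035,51.2711152248085,20.11963346507400,1,4,15,neg,neg,pos,symptomatic,none,10,censored
P00036,57.2698580869474,29.59392410935834,2,0,13,pos,neg,pos,symptomatic,endocrine,8.3556650308001,other_death
P00037,83.0297075002454,23.87235041940585,2,0,18,pos,,neg,symptomatic,both,9.20154790550557,other_death
P00038,74.4199216854759,6.43309139134362,2,0,15,pos,,pos,symptomatic,endocrine,10,censored
P00039,52.7352756983601,26.10491737956181,2,0,16,pos,,,symptomatic,endocrine,10,censored
P00040,57.6088379789144,15.34833092475310,1,0,5,pos,neg,pos,symptomatic,both,10,censored
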