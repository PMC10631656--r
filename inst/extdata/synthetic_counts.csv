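"occupation","site","culture","lat","lon","date_early","date_late","sequences","trait_01","trait_02","trait_03","trait_04","trait_05","trait_06","trait_07","trait_08","trait_09","trait_10","trait_11"
"SYC01","Synthetic site 01","CU1",44.0370285791917,-1.26976075927951,8087,7880,"1",9,6,41,11,1,0,20,0,14,84,14
"SYC02","Synthetic site 02","CU1",44.2402047981198,-0.753885981620201,7999,7790,"1",15,7,57,8,1,0,18,0,12,76,6
"SYC03","Synthetic site 03","CU1",42.6833322032406,0.190377165486181,7417,7127,"2",14,11,40,12,1,0,20,0,5,89,8
"SYC04","Synthetic site 04","CU1",44.5583760438724,-1.58404811780542,7829,7678,"1",12,10,51,10,0,0,20,0,12,83,2
"SYC05","Synthetic site 05","CU1",44.5619640044477,-2.30579955632674,8015,7832,"1",9,10,49,11,0,0,16,0,11,85,9
"SYC06","Synthetic site 06","CU1",43.9616799355988,-0.979550943658488,6950,6788,"2;3",10,12,45,7,2,0,20,0,17,77,10
"SYC07","Synthetic site 07","CU1",42.6176892646674,-0.848123224637958,8072,7811,"1",5,11,48,11,1,0,21,0,9,89,5
"SYC08","Synthetic site 08","CU1",43.8814653020091,0.481830572902919,7108,6813,"2;3",10,9,47,6,0,1,21,0,8,84,14
"SYC09","Synthetic site 09","CU1",44.8284729140069,-1.44269968303747,7752,7550,"1;2",3,7,43,14,1,0,19,0,8,97,8
"SYC10","Synthetic site 10","CU1",45.6965020630878,0.0214303879460389,7986,7719,"1",14,8,40,12,0,0,21,0,9,87,9
"SYC11","Synthetic site 11","CU1",44.0078576241246,-1.20957384680021,7920,7667,"1",12,11,48,9,0,0,19,0,4,89,8
"SYC12","Synthetic site 12","CU1",44.8179397945996,0.149193654646658,7975,7786,"1",6,9,48,8,0,0,16,0,11,92,10
"SYC13","Synthetic site 13","CU2",43.2553002156179,3.74008728449498,8167,7826,"1",8,26,0,12,0,12,79,8,26,22,7
"SYC14","Synthetic site 14","CU2",43.5842170392319,4.03701937026006,7052,6704,"2;3",10,30,0,14,0,7,76,3,29,24,7
"SYC15","Synthetic site 15","CU2",43.0653751250022,3.84265396896298,7654,7464,"1;2",5,29,0,11,2,6,78,11,29,23,6
"SYC16","Synthetic site 16","CU2",43.6460527254061,2.88158193955752,7924,7757,"1",4,31,0,18,1,5,61,6,27,37,10
"SYC17","Synthetic site 17","CU2",44.5690926051417,3.43926724744538,7075,6902,"2;3",6,27,0,11,1,8,61,6,35,36,9
"SYC18","Synthetic site 18","CU2",43.8720819456656,3.97725916979755,7593,7431,"2",5,23,0,17,0,11,64,5,37,33,5
"SYC19","Synthetic site 19","CU2",42.5898791680389,4.33056770430765,6646,6356,"3",1,36,0,14,2,8,69,7,31,25,7
"SYC20","Synthetic site 20","CU2",44.0485203936041,4.09112355854499,7831,7588,"1;2",1,39,0,20,0,8,63,6,32,24,7
"SYC21","Synthetic site 21","CU2",43.894594141538,4.1167956452888,7472,7197,"2",4,39,0,17,0,6,59,11,26,35,3
"SYC22","Synthetic site 22","CU2",41.2050510433687,4.99720689400333,7187,7013,"2",2,28,0,16,0,7,79,5,25,34,4
"SYC23","Synthetic site 23","CU2",43.4097162930439,2.27829394307637,7236,7010,"2",6,30,0,26,0,6,63,7,32,23,7
"SYC24","Synthetic site 24","CU2",42.7659727153404,2.42136305369217,7026,6679,"2;3",2,35,0,15,0,5,67,7,29,30,10
"SYC25","Synthetic site 25","CU3",41.5456559921907,8.96028664483647,6765,6473,"3",35,18,41,0,34,56,8,3,0,5,0
"SYC26","Synthetic site 26","CU3",42.5957328021881,9.90974349034623,7130,6863,"2;3",40,16,49,0,33,40,5,9,0,8,0
"SYC27","Synthetic site 27","CU3",43.9249641232605,9.34026866185824,6893,6722,"2;3",44,18,38,2,27,53,4,7,1,6,0
"SYC28","Synthetic site 28","CU3",41.1748577657371,8.62556017503867,6972,6709,"2;3",41,18,39,2,31,46,8,5,1,7,2
"SYC29","Synthetic site 29","CU3",42.3328536614833,7.91126881218707,7076,6883,"2;3",37,21,40,1,32,48,13,1,1,5,1
"SYC30","Synthetic site 30","CU3",41.4779270568043,9.1462945112624,7460,7237,"2",29,23,35,0,38,49,9,7,3,5,2
"SYC31","Synthetic site 31","CU3",42.5893748672346,10.1922813985795,6920,6579,"2;3",32,20,39,3,31,52,7,6,2,7,1
"SYC32","Synthetic site 32","CU3",41.1644530090321,9.12085543153102,7131,6784,"2;3",37,20,36,0,41,45,8,4,2,6,1
"SYC33","Synthetic site 33","CU3",41.397533568383,8.80803574029607,6905,6593,"2;3",41,18,51,1,26,41,6,8,1,6,1
"SYC34","Synthetic site 34","CU3",42.801808156479,8.94200517904503,6776,6619,"3",36,22,40,0,38,45,8,5,0,6,0
"SYC35","Synthetic site 35","CU3",40.9629605532111,8.84837598498394,7122,6819,"2;3",46,19,39,1,25,43,8,5,4,9,1
"SYC36","Synthetic site 36","CU3",41.4748694898508,10.6352917087006,7142,6820,"2;3",38,22,39,2,36,43,6,5,2,6,1
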