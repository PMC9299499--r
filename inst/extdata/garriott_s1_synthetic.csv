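dataset_id,covariate_level,dose,response,subject_id
garriott_synthetic,male,0,0.0820286106606037,male_0_01
garriott_synthetic,male,0,0.105979248295654,male_0_02
garriott_synthetic,male,0,0.0767782361604809,male_0_03
garriott_synthetic,male,0,0.165611100252946,male_0_04
garriott_synthetic,male,0,0.110982184957648,male_0_05
garriott_synthetic,male,1.14,0.0806220574562598,male_1.14_01
garriott_synthetic,male,1.14,0.121920081733158,male_1.14_02
garriott_synthetic,male,1.14,0.131987330125053,male_1.14_03
garriott_synthetic,male,1.14,0.125374494269099,male_1.14_04
garriott_synthetic,male,1.14,0.0948839792835731,male_1.14_05
garriott_synthetic,male,11.36,0.874744158316419,male_11.36_01
garriott_synthetic,male,11.36,0.613477462324802,male_11.36_02
garriott_synthetic,male,11.36,0.445595126029486,male_11.36_03
garriott_synthetic,male,11.36,0.269216172948138,male_11.36_04
garriott_synthetic,male,11.36,0.774020735025701,male_11.36_05
garriott_synthetic,male,57,8.57725361581282,male_57_01
garriott_synthetic,male,57,8.65557147650431,male_57_02
garriott_synthetic,male,57,11.7257847537659,male_57_03
garriott_synthetic,male,57,11.2798276826463,male_57_04
garriott_synthetic,male,57,10.4974368065775,male_57_05
garriott_synthetic,female,0,0.187213295380451,female_0_01
garriott_synthetic,female,0,0.179284806241655,female_0_02
garriott_synthetic,female,0,0.14334035980624,female_0_03
garriott_synthetic,female,0,0.0746308663743496,female_0_04
garriott_synthetic,female,0,0.170314807635593,female_0_05
garriott_synthetic,female,1.14,0.138234649674486,female_1.14_01
garriott_synthetic,female,1.14,0.133945794842517,female_1.14_02
garriott_synthetic,female,1.14,0.0883767853796224,female_1.14_03
garriott_synthetic,female,1.14,0.120964576109007,female_1.14_04
garriott_synthetic,female,1.14,0.16059196882726,female_1.14_05
garriott_synthetic,female,11.36,0.323370736614025,female_11.36_01
garriott_synthetic,female,11.36,0.203698900114892,female_11.36_02
garriott_synthetic,female,11.36,0.237873681969415,female_11.36_03
garriott_synthetic,female,11.36,0.206878695474302,female_11.36_04
garriott_synthetic,female,11.36,0.136139866818087,female_11.36_05
garriott_synthetic,female,57,1.63124525629087,female_57_01
garriott_synthetic,female,57,1.64196066713312,female_57_02
garriott_synthetic,female,57,1.8254379754464,female_57_03
garriott_synthetic,female,57,2.633819446406,female_57_04
garriott_synthetic,female,57,2.36768775885986,female_57_05
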