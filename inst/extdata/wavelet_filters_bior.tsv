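name	family	nfilt	dec_lo	rec_lo
bior1.1	biorthogonal	2	0.70710678118654757,0.70710678118654757	0.70710678118654757,0.70710678118654757
bior1.3	biorthogonal	6	-0.088388347648318447,0.088388347648318447,0.70710678118654757,0.70710678118654757,0.088388347648318447,-0.088388347648318447	0,0,0.70710678118654757,0.70710678118654757,0,0
bior1.5	biorthogonal	10	0.016572815184059706,-0.016572815184059706,-0.12153397801643785,0.12153397801643785,0.70710678118654757,0.70710678118654757,0.12153397801643785,-0.12153397801643785,-0.016572815184059706,0.016572815184059706	0,0,0,0,0.70710678118654757,0.70710678118654757,0,0,0,0
bior2.2	biorthogonal	6	0,-0.17677669529663689,0.35355339059327379,1.0606601717798212,0.35355339059327379,-0.17677669529663689	0,0.35355339059327379,0.70710678118654757,0.35355339059327379,0,0
bior2.4	biorthogonal	10	0,0.033145630368119412,-0.066291260736238825,-0.17677669529663689,0.4198446513295126,0.99436891104358249,0.4198446513295126,-0.17677669529663689,-0.066291260736238825,0.033145630368119412	0,0,0,0.35355339059327379,0.70710678118654757,0.35355339059327379,0,0,0,0
bior2.6	biorthogonal	14	0,-0.0069053396600248784,0.013810679320049757,0.046956309688169169,-0.1077232986963881,-0.16987135563661201,0.44746600996961211,0.96674755240348298,0.44746600996961211,-0.16987135563661201,-0.1077232986963881,0.046956309688169169,0.013810679320049757,-0.0069053396600248784	0,0,0,0,0,0.35355339059327379,0.70710678118654757,0.35355339059327379,0,0,0,0,0,0
bior2.8	biorthogonal	18	0,0.0015105430506304422,-0.0030210861012608843,-0.012947511862546647,0.028916109826354178,0.052998481890690938,-0.13491307360773605,-0.16382918343409023,0.46257144047591653,0.95164212189717856,0.46257144047591653,-0.16382918343409023,-0.13491307360773605,0.052998481890690938,0.028916109826354178,-0.012947511862546647,-0.0030210861012608843,0.0015105430506304422	0,0,0,0,0,0,0,0.35355339059327379,0.70710678118654757,0.35355339059327379,0,0,0,0,0,0,0,0
bior3.1	biorthogonal	4	-0.35355339059327379,1.0606601717798212,1.0606601717798212,-0.35355339059327379	0.17677669529663689,0.5303300858899106,0.5303300858899106,0.17677669529663689
bior3.3	biorthogonal	8	0.066291260736238825,-0.19887378220871649,-0.15467960838455727,0.99436891104358249,0.99436891104358249,-0.15467960838455727,-0.19887378220871649,0.066291260736238825	0,0,0.17677669529663689,0.5303300858899106,0.5303300858899106,0.17677669529663689,0,0
bior3.5	biorthogonal	12	-0.013810679320049757,0.041432037960149271,0.052480581416189075,-0.26792717880896527,-0.07181553246425873,0.96674755240348298,0.96674755240348298,-0.07181553246425873,-0.26792717880896527,0.052480581416189075,0.041432037960149271,-0.013810679320049757	0,0,0,0,0.17677669529663689,0.5303300858899106,0.5303300858899106,0.17677669529663689,0,0,0,0
bior3.7	biorthogonal	16	0.0030210861012608843,-0.0090632583037826529,-0.016831765421310641,0.074663985074019001,0.031332978707362888,-0.301159125922835,-0.026499240945345469,0.95164212189717856,0.95164212189717856,-0.026499240945345469,-0.301159125922835,0.031332978707362888,0.074663985074019001,-0.016831765421310641,-0.0090632583037826529,0.0030210861012608843	0,0,0,0,0,0,0.17677669529663689,0.5303300858899106,0.5303300858899106,0.17677669529663689,0,0,0,0,0,0
bior3.9	biorthogonal	20	-0.0006797443727836989,0.0020392331183510968,0.0050603192196119811,-0.020618912641105536,-0.014112787930175844,0.09913478249423216,0.012300136269419315,-0.32019196836077857,0.0020500227115698858,0.94212570067820678,0.94212570067820678,0.0020500227115698858,-0.32019196836077857,0.012300136269419315,0.09913478249423216,-0.014112787930175844,-0.020618912641105536,0.0050603192196119811,0.0020392331183510968,-0.0006797443727836989	0,0,0,0,0,0,0,0,0.17677669529663689,0.5303300858899106,0.5303300858899106,0.17677669529663689,0,0,0,0,0,0,0,0
bior4.4	biorthogonal	10	0,0.03782845550726404,-0.023849465019556843,-0.11062440441843718,0.37740285561283066,0.85269867900889385,0.37740285561283066,-0.11062440441843718,-0.023849465019556843,0.03782845550726404	0,-0.064538882628697058,-0.040689417609164058,0.41809227322161724,0.7884856164055829,0.41809227322161724,-0.040689417609164058,-0.064538882628697058,0,0
bior5.5	biorthogonal	12	0,0,0.03968708834740544,0.0079481086372403219,-0.054463788468236907,0.34560528195603346,0.73666018142821055,0.34560528195603346,-0.054463788468236907,0.0079481086372403219,0.03968708834740544,0	0.013456709459118716,-0.0026949668801115071,-0.13670658466432914,-0.093504697400938863,0.47680326579848425,0.89950610974864842,0.47680326579848425,-0.093504697400938863,-0.13670658466432914,-0.0026949668801115071,0.013456709459118716,0
bior6.8	biorthogonal	18	0,0.0019088317364812906,-0.0019142861290887667,-0.016990639867602342,0.01193456527972926,0.04973290349094079,-0.077263173167204144,-0.09405920349573646,0.42079628460982682,0.82592299745840225,0.42079628460982682,-0.09405920349573646,-0.077263173167204144,0.04973290349094079,0.01193456527972926,-0.016990639867602342,-0.0019142861290887667,0.0019088317364812906	0,0,0,0.014426282505624435,0.014467504896790148,-0.078722001062628819,-0.040367979030339923,0.41784910915027457,0.75890772945365415,0.41784910915027457,-0.040367979030339923,-0.078722001062628819,0.014467504896790148,0.014426282505624435,0,0,0,0
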