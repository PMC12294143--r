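canonical	count
Amidase_5 & NLPC_P60 & ZoocinA_TRD	60
ZoocinA_TRD	45
Amidase_5 & ZoocinA_TRD	30
Amidase_5 & NLPC_P60	25
CHAP	20
Glyco_hydro_25 & SH3_5	15
Amidase_5	12
CHAP & SH3_5	10
Glucosaminidase & ZoocinA_TRD	8
Amidase_5 & NLPC_P60 & CW_7 & Glucosaminidase	7
Glyco_hydro_25	5
Amidase_5 & SH3_5	4
CHAP & LysM	3
Glyco_hydro_25 & CW_7	1
NLPC_P60	1
Amidase_5 & LysM	1
Glucosaminidase & SH3_5	1
CHAP & ZoocinA_TRD	1
LysM	1
CHAP & PlyCA	1
PlyCB	1
Amidase_5 & CW_7	1
PGRP & pneumo_PspA	1
Glucosaminidase & LysM	1
NLPC_P60 & Glucosaminidase	1
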