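name	value	unit	note
d_Abi	1.8567123	/d	intraneural amyloid degradation; quasi-steady response to the driver
lambda_AboN	17382.993	-	necrosis leak weight on intraneural amyloid
d_AboM	55.231954	/d per g/cm3	microglial clearance of extraneural amyloid
d_Abo	0.67326686	/d	baseline extraneural amyloid clearance
lambda_AboA	22.477464	/d per g/cm3	astrocytic amyloid secretion (bilinear term)
lambda_tauAbi	7.8358006e-05	/d	amyloid-driven tau hyperphosphorylation
d_tau	1.3885018	/d	tau degradation
delta_MAbo	2.0e-04	cm/d	chemotactic speed bound of microglia
K_gradAbo	1.0e-04	g/cm4	flux-limiter gradient constant
D_M	1.0e-05	cm2/d	microglia diffusivity
lambda_MAbo	0.027405005	/d	microglial activation by amyloid excess
K_Abo	5.7566698e-06	g/cm3	amyloid-excess Hill constant (activation and death)
lambda_MFi	0.026624754	/d	microglial activation by tangles
K_Fi	2.2304061e-10	g/cm3	tangle Hill constant (activation and death)
d_M	0.048743745	/d	microglia turnover
lambda_AM	0.0088647067	/d	astrocyte activation by microglia
K_M	0.008857311	g/cm3	microglia Hill constant of astrocyte activation
d_A	0.010158817	/d	astrocyte turnover
d_NFi	1.2152498e-04	/d	tangle-driven neuron death rate
d_NAbo	1.1234320e-04	/d	amyloid-driven neuron death rate
D_Abi	1.0e-06	cm2/d	intraneural amyloid diffusivity
D_Abo	1.0e-05	cm2/d	extraneural amyloid diffusivity
D_tau	1.0e-06	cm2/d	tau diffusivity
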