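[settings]
dt	0.0001
record_rate	1000
duration	10
H	31.5

[population]
label	Q_max	theta	sigma_prime	alpha	beta
cortex_excitatory	340	0.013	0.0038	50	200
cortex_inhibitory	340	0.013	0.0038	50	200
striatum_D1	65	0.019	0.0038	50	200
striatum_D2	65	0.019	0.0038	50	200
GPi_SNr	250	0.010	0.0038	50	200
GPe	300	0.009	0.0038	50	200
STN	500	0.010	0.0038	50	200
relay_nuclei	300	0.013	0.0038	50	200
TRN	500	0.013	0.0038	50	200

[projection]
source	target	nu	tau	gamma
cortex_excitatory	cortex_excitatory	0.0012000	0.002	125
cortex_excitatory	cortex_inhibitory	0.0012000	0.002	125
cortex_excitatory	striatum_D1	0.0005000	0.002	125
cortex_excitatory	striatum_D2	0.0005000	0.002	125
cortex_excitatory	STN	0.0003000	0.002	125
cortex_excitatory	relay_nuclei	0.0005848	0.040	125
cortex_excitatory	TRN	0.0002924	0.040	125
cortex_inhibitory	cortex_excitatory	-0.0018000	0.001	400
cortex_inhibitory	cortex_inhibitory	-0.0018000	0.001	400
striatum_D1	striatum_D1	-0.0003000	0.001	400
striatum_D1	GPi_SNr	-0.0001000	0.001	400
striatum_D2	striatum_D2	-0.0003000	0.001	400
striatum_D2	GPe	-0.0003000	0.001	400
GPi_SNr	relay_nuclei	-0.0000500	0.002	400
GPe	GPi_SNr	-0.0000300	0.001	400
GPe	STN	-0.0000500	0.001	400
GPe	GPe	-0.0000500	0.001	400
GPe	cortex_inhibitory	-0.0000200	0.002	400
GPe	relay_nuclei	-0.0000200	0.002	400
GPe	TRN	-0.0000200	0.002	400
GPe	striatum_D1	-0.0000200	0.002	400
GPe	striatum_D2	-0.0000200	0.002	400
STN	GPi_SNr	0.0001000	0.001	400
STN	GPe	0.0001000	0.001	400
relay_nuclei	cortex_excitatory	0.0005848	0.040	400
relay_nuclei	cortex_inhibitory	0.0004000	0.040	400
relay_nuclei	striatum_D1	0.0003000	0.002	400
relay_nuclei	striatum_D2	0.0003000	0.002	400
relay_nuclei	TRN	0.0002924	0.002	400
TRN	relay_nuclei	-0.0002924	0.002	400

[external]
label	mean	noise_sd
cortex_excitatory	0.00686933245922	0e+00
cortex_inhibitory	0.01313379580758	0e+00
striatum_D1	0.00311771800382	0e+00
striatum_D2	0.00311771800382	0e+00
GPi_SNr	0.00691474584503	0e+00
GPe	0.00250630691682	0e+00
STN	-0.00435426155418	0e+00
relay_nuclei	0.00657267117087	5e-05
TRN	-0.00653080751656	0e+00

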