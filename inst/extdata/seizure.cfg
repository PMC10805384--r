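[settings]
dt	0.0001
record_rate	1000
duration	10
H	31.5

[population]
label	Q_max	theta	sigma_prime	alpha	beta
cortex_excitatory	340	0.013	0.0038	35	140
cortex_inhibitory	340	0.013	0.0038	35	140
striatum_D1	65	0.019	0.0038	35	140
striatum_D2	65	0.019	0.0038	35	140
GPi_SNr	250	0.010	0.0038	35	140
GPe	300	0.009	0.0038	35	140
STN	500	0.010	0.0038	35	140
relay_nuclei	300	0.013	0.0038	35	140
TRN	500	0.013	0.0038	35	140

[projection]
source	target	nu	tau	gamma
cortex_excitatory	cortex_excitatory	0.001200	0.002	125
cortex_excitatory	cortex_inhibitory	0.001200	0.002	125
cortex_excitatory	striatum_D1	0.000375	0.002	125
cortex_excitatory	striatum_D2	0.000375	0.002	125
cortex_excitatory	STN	0.000300	0.002	125
cortex_excitatory	relay_nuclei	0.000492	0.040	125
cortex_excitatory	TRN	0.000246	0.040	125
cortex_inhibitory	cortex_excitatory	-0.001800	0.001	400
cortex_inhibitory	cortex_inhibitory	-0.001800	0.001	400
striatum_D1	striatum_D1	-0.000300	0.001	400
striatum_D1	GPi_SNr	-0.000100	0.001	400
striatum_D2	striatum_D2	-0.000300	0.001	400
striatum_D2	GPe	-0.000300	0.001	400
GPi_SNr	relay_nuclei	-0.000050	0.002	400
GPe	GPi_SNr	-0.000030	0.001	400
GPe	STN	-0.000050	0.001	400
GPe	GPe	-0.000050	0.001	400
GPe	cortex_inhibitory	-0.000020	0.002	400
GPe	relay_nuclei	-0.000020	0.002	400
GPe	TRN	-0.000020	0.002	400
GPe	striatum_D1	-0.000020	0.002	400
GPe	striatum_D2	-0.000020	0.002	400
STN	GPi_SNr	0.000100	0.001	400
STN	GPe	0.000100	0.001	400
relay_nuclei	cortex_excitatory	0.000492	0.040	400
relay_nuclei	cortex_inhibitory	0.000400	0.040	400
relay_nuclei	striatum_D1	0.000225	0.002	400
relay_nuclei	striatum_D2	0.000225	0.002	400
relay_nuclei	TRN	0.000246	0.002	400
TRN	relay_nuclei	-0.000246	0.002	400

[external]
label	mean	noise_sd
cortex_excitatory	0.01254616016251	0.000
cortex_inhibitory	0.01820025612312	0.000
striatum_D1	0.00342323714728	0.000
striatum_D2	0.00342323714728	0.000
GPi_SNr	0.00695010520346	0.000
GPe	0.00325099643532	0.000
STN	-0.00468321073717	0.000
relay_nuclei	0.00846037973816	0.002
TRN	-0.00768844976734	0.000

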