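population_id	name	latitude	longitude	n_sampled
SE-58	Saleby	58.36	13.12	8
SE-60	SorAmsberg	60.45	15.42	8
SE-61	Fulufjallet	61.57	12.78	24
SE-62	Strangsund	62.63	15.12	8
SE-64	Hoglunda	64.08	18.74	24
SE-66	Jock/Erkinvinsa	66.58	22.70	8
FI-61	Punkaharju	61.72	29.39	8
FI-62	Vilpuula	62.02	24.63	8
FI-66	St2	66.24	26.53	8
FI-67	Sodankyla	67.41	26.62	24
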