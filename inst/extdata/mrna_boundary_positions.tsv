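gene	time_class	domain	boundary	position
hb	C13	anterior	P	45.8
gt	C13	anterior	A	19.3
gt	C13	anterior	P	39.8
Kr	C13	central	A	46.7
Kr	C13	central	P	59.4
kni	C13	abdominal	A	58.3
kni	C13	abdominal	P	72.0
gt	C13	posterior	A	74.0
hb	C13	posterior	A	89.5
hb	T1	anterior	P	43.8
gt	T1	anterior	A	20.7
gt	T1	anterior	P	39.3
Kr	T1	central	A	45.3
Kr	T1	central	P	57.8
kni	T1	abdominal	A	56.5
kni	T1	abdominal	P	70.1
gt	T1	posterior	A	69.8
gt	T1	posterior	P	82.2
hb	T1	posterior	A	85.0
hb	T2	anterior	P	44.4
gt	T2	anterior	A	20.0
gt	T2	anterior	P	38.2
Kr	T2	central	A	44.3
Kr	T2	central	P	57.3
kni	T2	abdominal	A	57.9
kni	T2	abdominal	P	70.1
gt	T2	posterior	A	69.8
gt	T2	posterior	P	79.4
hb	T2	posterior	A	81.2
hb	T2	posterior	P	92.2
hb	T3	anterior	P	45.1
gt	T3	anterior	A	18.7
gt	T3	anterior	P	37.8
Kr	T3	central	A	45.5
Kr	T3	central	P	59.8
kni	T3	abdominal	A	58.0
kni	T3	abdominal	P	70.0
gt	T3	posterior	A	67.5
gt	T3	posterior	P	76.9
hb	T3	posterior	A	80.1
hb	T3	posterior	P	89.3
hb	T4	anterior	P	47.0
gt	T4	anterior	A	18.2
gt	T4	anterior	P	37.7
Kr	T4	central	A	44.0
Kr	T4	central	P	57.8
kni	T4	abdominal	A	56.9
kni	T4	abdominal	P	67.1
gt	T4	posterior	A	67.0
gt	T4	posterior	P	77.0
hb	T4	posterior	A	78.9
hb	T4	posterior	P	88.0
hb	T5	anterior	P	45.9
gt	T5	anterior	A	18.3
gt	T5	anterior	P	37.7
Kr	T5	central	A	43.9
Kr	T5	central	P	56.7
kni	T5	abdominal	A	56.0
kni	T5	abdominal	P	66.0
gt	T5	posterior	A	66.8
gt	T5	posterior	P	76.5
hb	T5	posterior	A	76.9
hb	T5	posterior	P	87.7
hb	T6	anterior	P	45.8
gt	T6	anterior	A	18.8
gt	T6	anterior	P	37.3
Kr	T6	central	A	43.5
Kr	T6	central	P	56.4
kni	T6	abdominal	A	54.5
kni	T6	abdominal	P	64.8
gt	T6	posterior	A	65.6
gt	T6	posterior	P	75.1
hb	T6	posterior	A	75.0
hb	T6	posterior	P	86.6
hb	T7	anterior	P	45.8
gt	T7	anterior	A	19.7
gt	T7	anterior	P	37.6
Kr	T7	central	A	43.0
Kr	T7	central	P	52.5
kni	T7	abdominal	A	54.5
kni	T7	abdominal	P	63.0
gt	T7	posterior	A	64.5
gt	T7	posterior	P	72.1
hb	T7	posterior	A	75.6
hb	T7	posterior	P	86.1
hb	T8	anterior	P	45.0
gt	T8	anterior	A	20.5
gt	T8	anterior	P	37.2
Kr	T8	central	A	42.7
Kr	T8	central	P	52.5
kni	T8	abdominal	A	54.7
kni	T8	abdominal	P	63.6
gt	T8	posterior	A	65.3
gt	T8	posterior	P	72.8
hb	T8	posterior	A	75.5
hb	T8	posterior	P	85.8
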