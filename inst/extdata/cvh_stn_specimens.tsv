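# Per-specimen axis-aligned STN extents and gravity centers, AC-PC frame, mm.
# Transcribed values for the four cryosection head specimens.
specimen	side	axis	min_mm	max_mm	gravity_mm
CVH-1	left	x	-15.57	-5.52	-10.7
CVH-1	left	y	-5.19	4.02	-1.6
CVH-1	left	z	-8.04	-2.01	-5.4
CVH-1	right	x	5.36	15.07	10.0
CVH-1	right	y	-4.35	4.69	-0.1
CVH-1	right	z	-8.04	-2.01	-4.9
CVH-2	left	x	-13.51	-6.45	-9.5
CVH-2	left	y	-5.07	2.61	-1.4
CVH-2	left	z	-6.91	-0.77	-3.3
CVH-2	right	x	6.6	13.66	9.5
CVH-2	right	y	-5.07	2.61	-1.0
CVH-2	right	z	-6.97	-0.77	-3.4
CVH-4	left	x	-13.72	-4.23	-10.0
CVH-4	left	y	-6.54	3.97	-2.0
CVH-4	left	z	-6.79	-0.64	-3.6
CVH-4	right	x	5.13	13.97	10.3
CVH-4	right	y	-6.03	4.23	-1.2
CVH-4	right	z	-6.28	-0.13	-3.2
CVH-5	left	x	-12.61	-3.64	-8.3
CVH-5	left	y	-5.07	6.37	0.8
CVH-5	left	z	-7.15	0.39	-3.5
CVH-5	right	x	4.42	12.87	9.5
CVH-5	right	y	-5.46	6.11	-0.3
CVH-5	right	z	-7.54	0.26	-3.5
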