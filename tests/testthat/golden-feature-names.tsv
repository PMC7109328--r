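F1	aac.A
F2	aac.C
F3	aac.D
F4	aac.E
F5	aac.F
F6	aac.G
F7	aac.H
F8	aac.I
F9	aac.K
F10	aac.L
F11	aac.M
F12	aac.N
F13	aac.P
F14	aac.Q
F15	aac.R
F16	aac.S
F17	aac.T
F18	aac.V
F19	aac.W
F20	aac.Y
F21	hydrophobicity.comp.c1
F22	hydrophobicity.comp.c2
F23	hydrophobicity.comp.c3
F24	hydrophobicity.dist.c1.qfirst
F25	hydrophobicity.dist.c1.q25
F26	hydrophobicity.dist.c1.q50
F27	hydrophobicity.dist.c1.q75
F28	hydrophobicity.dist.c1.q100
F29	hydrophobicity.dist.c2.qfirst
F30	hydrophobicity.dist.c2.q25
F31	hydrophobicity.dist.c2.q50
F32	hydrophobicity.dist.c2.q75
F33	hydrophobicity.dist.c2.q100
F34	hydrophobicity.dist.c3.qfirst
F35	hydrophobicity.dist.c3.q25
F36	hydrophobicity.dist.c3.q50
F37	hydrophobicity.dist.c3.q75
F38	hydrophobicity.dist.c3.q100
F39	hydrophobicity.trans.c1c2
F40	hydrophobicity.trans.c1c3
F41	hydrophobicity.trans.c2c3
F42	normalized_vdw_volume.comp.c1
F43	normalized_vdw_volume.comp.c2
F44	normalized_vdw_volume.comp.c3
F45	normalized_vdw_volume.dist.c1.qfirst
F46	normalized_vdw_volume.dist.c1.q25
F47	normalized_vdw_volume.dist.c1.q50
F48	normalized_vdw_volume.dist.c1.q75
F49	normalized_vdw_volume.dist.c1.q100
F50	normalized_vdw_volume.dist.c2.qfirst
F51	normalized_vdw_volume.dist.c2.q25
F52	normalized_vdw_volume.dist.c2.q50
F53	normalized_vdw_volume.dist.c2.q75
F54	normalized_vdw_volume.dist.c2.q100
F55	normalized_vdw_volume.dist.c3.qfirst
F56	normalized_vdw_volume.dist.c3.q25
F57	normalized_vdw_volume.dist.c3.q50
F58	normalized_vdw_volume.dist.c3.q75
F59	normalized_vdw_volume.dist.c3.q100
F60	normalized_vdw_volume.trans.c1c2
F61	normalized_vdw_volume.trans.c1c3
F62	normalized_vdw_volume.trans.c2c3
F63	polarity.comp.c1
F64	polarity.comp.c2
F65	polarity.comp.c3
F66	polarity.dist.c1.qfirst
F67	polarity.dist.c1.q25
F68	polarity.dist.c1.q50
F69	polarity.dist.c1.q75
F70	polarity.dist.c1.q100
F71	polarity.dist.c2.qfirst
F72	polarity.dist.c2.q25
F73	polarity.dist.c2.q50
F74	polarity.dist.c2.q75
F75	polarity.dist.c2.q100
F76	polarity.dist.c3.qfirst
F77	polarity.dist.c3.q25
F78	polarity.dist.c3.q50
F79	polarity.dist.c3.q75
F80	polarity.dist.c3.q100
F81	polarity.trans.c1c2
F82	polarity.trans.c1c3
F83	polarity.trans.c2c3
F84	polarizability.comp.c1
F85	polarizability.comp.c2
F86	polarizability.comp.c3
F87	polarizability.dist.c1.qfirst
F88	polarizability.dist.c1.q25
F89	polarizability.dist.c1.q50
F90	polarizability.dist.c1.q75
F91	polarizability.dist.c1.q100
F92	polarizability.dist.c2.qfirst
F93	polarizability.dist.c2.q25
F94	polarizability.dist.c2.q50
F95	polarizability.dist.c2.q75
F96	polarizability.dist.c2.q100
F97	polarizability.dist.c3.qfirst
F98	polarizability.dist.c3.q25
F99	polarizability.dist.c3.q50
F100	polarizability.dist.c3.q75
F101	polarizability.dist.c3.q100
F102	polarizability.trans.c1c2
F103	polarizability.trans.c1c3
F104	polarizability.trans.c2c3
F105	charge.comp.c1
F106	charge.comp.c2
F107	charge.comp.c3
F108	charge.dist.c1.qfirst
F109	charge.dist.c1.q25
F110	charge.dist.c1.q50
F111	charge.dist.c1.q75
F112	charge.dist.c1.q100
F113	charge.dist.c2.qfirst
F114	charge.dist.c2.q25
F115	charge.dist.c2.q50
F116	charge.dist.c2.q75
F117	charge.dist.c2.q100
F118	charge.dist.c3.qfirst
F119	charge.dist.c3.q25
F120	charge.dist.c3.q50
F121	charge.dist.c3.q75
F122	charge.dist.c3.q100
F123	charge.trans.c1c2
F124	charge.trans.c1c3
F125	charge.trans.c2c3
F126	surface_tension.comp.c1
F127	surface_tension.comp.c2
F128	surface_tension.comp.c3
F129	surface_tension.dist.c1.qfirst
F130	surface_tension.dist.c1.q25
F131	surface_tension.dist.c1.q50
F132	surface_tension.dist.c1.q75
F133	surface_tension.dist.c1.q100
F134	surface_tension.dist.c2.qfirst
F135	surface_tension.dist.c2.q25
F136	surface_tension.dist.c2.q50
F137	surface_tension.dist.c2.q75
F138	surface_tension.dist.c2.q100
F139	surface_tension.dist.c3.qfirst
F140	surface_tension.dist.c3.q25
F141	surface_tension.dist.c3.q50
F142	surface_tension.dist.c3.q75
F143	surface_tension.dist.c3.q100
F144	surface_tension.trans.c1c2
F145	surface_tension.trans.c1c3
F146	surface_tension.trans.c2c3
F147	secondary_structure.comp.c1
F148	secondary_structure.comp.c2
F149	secondary_structure.comp.c3
F150	secondary_structure.dist.c1.qfirst
F151	secondary_structure.dist.c1.q25
F152	secondary_structure.dist.c1.q50
F153	secondary_structure.dist.c1.q75
F154	secondary_structure.dist.c1.q100
F155	secondary_structure.dist.c2.qfirst
F156	secondary_structure.dist.c2.q25
F157	secondary_structure.dist.c2.q50
F158	secondary_structure.dist.c2.q75
F159	secondary_structure.dist.c2.q100
F160	secondary_structure.dist.c3.qfirst
F161	secondary_structure.dist.c3.q25
F162	secondary_structure.dist.c3.q50
F163	secondary_structure.dist.c3.q75
F164	secondary_structure.dist.c3.q100
F165	secondary_structure.trans.c1c2
F166	secondary_structure.trans.c1c3
F167	secondary_structure.trans.c2c3
F168	solvent_accessibility.comp.c1
F169	solvent_accessibility.comp.c2
F170	solvent_accessibility.comp.c3
F171	solvent_accessibility.dist.c1.qfirst
F172	solvent_accessibility.dist.c1.q25
F173	solvent_accessibility.dist.c1.q50
F174	solvent_accessibility.dist.c1.q75
F175	solvent_accessibility.dist.c1.q100
F176	solvent_accessibility.dist.c2.qfirst
F177	solvent_accessibility.dist.c2.q25
F178	solvent_accessibility.dist.c2.q50
F179	solvent_accessibility.dist.c2.q75
F180	solvent_accessibility.dist.c2.q100
F181	solvent_accessibility.dist.c3.qfirst
F182	solvent_accessibility.dist.c3.q25
F183	solvent_accessibility.dist.c3.q50
F184	solvent_accessibility.dist.c3.q75
F185	solvent_accessibility.dist.c3.q100
F186	solvent_accessibility.trans.c1c2
F187	solvent_accessibility.trans.c1c3
F188	solvent_accessibility.trans.c2c3
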