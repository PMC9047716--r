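label,hemisphere,name
2,L,Left-Cerebral-White-Matter
4,L,Left-Lateral-Ventricle
5,L,Left-Inf-Lat-Vent
7,L,Left-Cerebellum-White-Matter
8,L,Left-Cerebellum-Cortex
10,L,Left-Thalamus-Proper
11,L,Left-Caudate
12,L,Left-Putamen
13,L,Left-Pallidum
14,NA,3rd-Ventricle
15,NA,4th-Ventricle
16,NA,Brain-Stem
17,L,Left-Hippocampus
18,L,Left-Amygdala
24,NA,CSF
26,L,Left-Accumbens-area
28,L,Left-VentralDC
30,L,Left-vessel
31,L,Left-choroid-plexus
41,R,Right-Cerebral-White-Matter
43,R,Right-Lateral-Ventricle
44,R,Right-Inf-Lat-Vent
46,R,Right-Cerebellum-White-Matter
47,R,Right-Cerebellum-Cortex
49,R,Right-Thalamus-Proper
50,R,Right-Caudate
51,R,Right-Putamen
52,R,Right-Pallidum
53,R,Right-Hippocampus
54,R,Right-Amygdala
58,R,Right-Accumbens-area
60,R,Right-VentralDC
62,R,Right-vessel
63,R,Right-choroid-plexus
72,NA,5th-Ventricle
77,NA,WM-hypointensities
80,NA,non-WM-hypointensities
85,NA,Optic-Chiasm
251,NA,CC_Posterior
252,NA,CC_Mid_Posterior
253,NA,CC_Central
254,NA,CC_Mid_Anterior
255,NA,CC_Anterior
11101,L,ctx_lh_G_and_S_frontomargin
11102,L,ctx_lh_G_and_S_occipital_inf
11103,L,ctx_lh_G_and_S_paracentral
11104,L,ctx_lh_G_and_S_subcentral
11105,L,ctx_lh_G_and_S_transv_frontopol
11106,L,ctx_lh_G_and_S_cingul-Ant
11107,L,ctx_lh_G_and_S_cingul-Mid-Ant
11108,L,ctx_lh_G_and_S_cingul-Mid-Post
11109,L,ctx_lh_G_cingul-Post-dorsal
11110,L,ctx_lh_G_cingul-Post-ventral
11111,L,ctx_lh_G_cuneus
11112,L,ctx_lh_G_front_inf-Opercular
11113,L,ctx_lh_G_front_inf-Orbital
11114,L,ctx_lh_G_front_inf-Triangul
11115,L,ctx_lh_G_front_middle
11116,L,ctx_lh_G_front_sup
11117,L,ctx_lh_G_Ins_lg_and_S_cent_ins
11118,L,ctx_lh_G_insular_short
11119,L,ctx_lh_G_occipital_middle
11120,L,ctx_lh_G_occipital_sup
11121,L,ctx_lh_G_oc-temp_lat-fusifor
11122,L,ctx_lh_G_oc-temp_med-Lingual
11123,L,ctx_lh_G_oc-temp_med-Parahip
11124,L,ctx_lh_G_orbital
11125,L,ctx_lh_G_pariet_inf-Angular
11126,L,ctx_lh_G_pariet_inf-Supramar
11127,L,ctx_lh_G_parietal_sup
11128,L,ctx_lh_G_postcentral
11129,L,ctx_lh_G_precentral
11130,L,ctx_lh_G_precuneus
11131,L,ctx_lh_G_rectus
11132,L,ctx_lh_G_subcallosal
11133,L,ctx_lh_G_temp_sup-G_T_transv
11134,L,ctx_lh_G_temp_sup-Lateral
11135,L,ctx_lh_G_temp_sup-Plan_polar
11136,L,ctx_lh_G_temp_sup-Plan_tempo
11137,L,ctx_lh_G_temporal_inf
11138,L,ctx_lh_G_temporal_middle
11139,L,ctx_lh_Lat_Fis-ant-Horizont
11140,L,ctx_lh_Lat_Fis-ant-Vertical
11141,L,ctx_lh_Lat_Fis-post
11143,L,ctx_lh_Pole_occipital
11144,L,ctx_lh_Pole_temporal
11145,L,ctx_lh_S_calcarine
11146,L,ctx_lh_S_central
11147,L,ctx_lh_S_cingul-Marginalis
11148,L,ctx_lh_S_circular_insula_ant
11149,L,ctx_lh_S_circular_insula_inf
11150,L,ctx_lh_S_circular_insula_sup
11151,L,ctx_lh_S_collat_transv_ant
11152,L,ctx_lh_S_collat_transv_post
11153,L,ctx_lh_S_front_inf
11154,L,ctx_lh_S_front_middle
11155,L,ctx_lh_S_front_sup
11156,L,ctx_lh_S_interm_prim-Jensen
11157,L,ctx_lh_S_intrapariet_and_P_trans
11158,L,ctx_lh_S_oc_middle_and_Lunatus
11159,L,ctx_lh_S_oc_sup_and_transversal
11160,L,ctx_lh_S_occipital_ant
11161,L,ctx_lh_S_oc-temp_lat
11162,L,ctx_lh_S_oc-temp_med_and_Lingual
11163,L,ctx_lh_S_orbital_lateral
11164,L,ctx_lh_S_orbital_med-olfact
11165,L,ctx_lh_S_orbital-H_Shaped
11166,L,ctx_lh_S_parieto_occipital
11167,L,ctx_lh_S_pericallosal
11168,L,ctx_lh_S_postcentral
11169,L,ctx_lh_S_precentral-inf-part
11170,L,ctx_lh_S_precentral-sup-part
11171,L,ctx_lh_S_suborbital
11172,L,ctx_lh_S_subparietal
11173,L,ctx_lh_S_temporal_inf
11174,L,ctx_lh_S_temporal_sup
11175,L,ctx_lh_S_temporal_transverse
12101,R,ctx_rh_G_and_S_frontomargin
12102,R,ctx_rh_G_and_S_occipital_inf
12103,R,ctx_rh_G_and_S_paracentral
12104,R,ctx_rh_G_and_S_subcentral
12105,R,ctx_rh_G_and_S_transv_frontopol
12106,R,ctx_rh_G_and_S_cingul-Ant
12107,R,ctx_rh_G_and_S_cingul-Mid-Ant
12108,R,ctx_rh_G_and_S_cingul-Mid-Post
12109,R,ctx_rh_G_cingul-Post-dorsal
12110,R,ctx_rh_G_cingul-Post-ventral
12111,R,ctx_rh_G_cuneus
12112,R,ctx_rh_G_front_inf-Opercular
12113,R,ctx_rh_G_front_inf-Orbital
12114,R,ctx_rh_G_front_inf-Triangul
12115,R,ctx_rh_G_front_middle
12116,R,ctx_rh_G_front_sup
12117,R,ctx_rh_G_Ins_lg_and_S_cent_ins
12118,R,ctx_rh_G_insular_short
12119,R,ctx_rh_G_occipital_middle
12120,R,ctx_rh_G_occipital_sup
12121,R,ctx_rh_G_oc-temp_lat-fusifor
12122,R,ctx_rh_G_oc-temp_med-Lingual
12123,R,ctx_rh_G_oc-temp_med-Parahip
12124,R,ctx_rh_G_orbital
12125,R,ctx_rh_G_pariet_inf-Angular
12126,R,ctx_rh_G_pariet_inf-Supramar
12127,R,ctx_rh_G_parietal_sup
12128,R,ctx_rh_G_postcentral
12129,R,ctx_rh_G_precentral
12130,R,ctx_rh_G_precuneus
12131,R,ctx_rh_G_rectus
12132,R,ctx_rh_G_subcallosal
12133,R,ctx_rh_G_temp_sup-G_T_transv
12134,R,ctx_rh_G_temp_sup-Lateral
12135,R,ctx_rh_G_temp_sup-Plan_polar
12136,R,ctx_rh_G_temp_sup-Plan_tempo
12137,R,ctx_rh_G_temporal_inf
12138,R,ctx_rh_G_temporal_middle
12139,R,ctx_rh_Lat_Fis-ant-Horizont
12140,R,ctx_rh_Lat_Fis-ant-Vertical
12141,R,ctx_rh_Lat_Fis-post
12143,R,ctx_rh_Pole_occipital
12144,R,ctx_rh_Pole_temporal
12145,R,ctx_rh_S_calcarine
12146,R,ctx_rh_S_central
12147,R,ctx_rh_S_cingul-Marginalis
12148,R,ctx_rh_S_circular_insula_ant
12149,R,ctx_rh_S_circular_insula_inf
12150,R,ctx_rh_S_circular_insula_sup
12151,R,ctx_rh_S_collat_transv_ant
12152,R,ctx_rh_S_collat_transv_post
12153,R,ctx_rh_S_front_inf
12154,R,ctx_rh_S_front_middle
12155,R,ctx_rh_S_front_sup
12156,R,ctx_rh_S_interm_prim-Jensen
12157,R,ctx_rh_S_intrapariet_and_P_trans
12158,R,ctx_rh_S_oc_middle_and_Lunatus
12159,R,ctx_rh_S_oc_sup_and_transversal
12160,R,ctx_rh_S_occipital_ant
12161,R,ctx_rh_S_oc-temp_lat
12162,R,ctx_rh_S_oc-temp_med_and_Lingual
12163,R,ctx_rh_S_orbital_lateral
12164,R,ctx_rh_S_orbital_med-olfact
12165,R,ctx_rh_S_orbital-H_Shaped
12166,R,ctx_rh_S_parieto_occipital
12167,R,ctx_rh_S_pericallosal
12168,R,ctx_rh_S_postcentral
12169,R,ctx_rh_S_precentral-inf-part
12170,R,ctx_rh_S_precentral-sup-part
12171,R,ctx_rh_S_suborbital
12172,R,ctx_rh_S_subparietal
12173,R,ctx_rh_S_temporal_inf
12174,R,ctx_rh_S_temporal_sup
12175,R,ctx_rh_S_temporal_transverse
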