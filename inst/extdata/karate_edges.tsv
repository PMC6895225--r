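v01	v02	1
v01	v03	1
v01	v04	1
v01	v05	1
v01	v06	1
v01	v07	1
v01	v08	1
v01	v09	1
v01	v11	1
v01	v12	1
v01	v13	1
v01	v14	1
v01	v18	1
v01	v20	1
v01	v22	1
v01	v32	1
v02	v03	1
v02	v04	1
v02	v08	1
v02	v14	1
v02	v18	1
v02	v20	1
v02	v22	1
v02	v31	1
v03	v04	1
v03	v08	1
v03	v09	1
v03	v10	1
v03	v14	1
v03	v28	1
v03	v29	1
v03	v33	1
v04	v08	1
v04	v13	1
v04	v14	1
v05	v07	1
v05	v11	1
v06	v07	1
v06	v11	1
v06	v17	1
v07	v17	1
v09	v31	1
v09	v33	1
v09	v34	1
v10	v34	1
v14	v34	1
v15	v33	1
v15	v34	1
v16	v33	1
v16	v34	1
v19	v33	1
v19	v34	1
v20	v34	1
v21	v33	1
v21	v34	1
v23	v33	1
v23	v34	1
v24	v26	1
v24	v28	1
v24	v30	1
v24	v33	1
v24	v34	1
v25	v26	1
v25	v28	1
v25	v32	1
v26	v32	1
v27	v30	1
v27	v34	1
v28	v34	1
v29	v32	1
v29	v34	1
v30	v33	1
v30	v34	1
v31	v33	1
v31	v34	1
v32	v33	1
v32	v34	1
v33	v34	1
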