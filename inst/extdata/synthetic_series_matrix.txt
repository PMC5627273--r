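!Series_title	"synthetic example (generated by interplayr, not a real accession)"
!series_matrix_table_begin
"ID_REF"	"PBS_2h_r1"	"PBS_2h_r2"	"PBS_2h_r3"	"MPL_2h_r1"	"MPL_2h_r2"	"MPL_2h_r3"	"QS21_2h_r1"	"QS21_2h_r2"	"QS21_2h_r3"	"AS01_2h_r1"	"AS01_2h_r2"	"AS01_2h_r3"	"PBS_4h_r1"	"PBS_4h_r2"	"PBS_4h_r3"	"MPL_4h_r1"	"MPL_4h_r2"	"MPL_4h_r3"	"QS21_4h_r1"	"QS21_4h_r2"	"QS21_4h_r3"	"AS01_4h_r1"	"AS01_4h_r2"	"AS01_4h_r3"
"gene00001"	8.682	8.523	8.369	8.554	8.616	8.429	11.52	11.67	11.53	11.65	11.53	11.47	8.605	8.446	8.662	8.461	8.39	8.587	11.64	11.5	11.56	11.68	11.56	11.83
"gene00002"	6.85	6.737	6.701	6.821	7.037	6.772	9.985	9.635	9.907	9.88	9.975	9.781	6.743	7.137	7.005	6.865	6.714	6.74	9.931	9.904	10.29	10.23	9.881	9.685
"gene00003"	7.728	8.061	8.175	10.93	11.39	10.95	7.944	8.098	8.008	11.07	11.21	11.08	8.487	7.994	8.343	11.19	11.51	11.43	8.237	7.978	8.201	11.26	10.68	11.21
"gene00004"	7.696	7.889	7.696	10.96	10.89	11.22	7.795	7.732	8.087	10.97	10.97	11.2	7.832	8.136	7.627	10.79	10.6	10.72	8.077	7.787	7.903	10.82	11.2	11.44
"gene00005"	7.45	7.138	7.274	8.935	8.876	9.037	8.791	8.843	8.866	10.06	9.976	10.45	7.407	7.201	7.382	8.912	8.761	8.786	8.682	8.671	8.595	10.41	10.24	10.25
"gene00006"	5.115	5.683	5.592	6.965	6.936	7.026	6.451	6.891	7.83	8.691	8.493	8.796	5.458	5.975	5.247	7.551	7.303	7.218	6.466	7.206	6.648	8.541	8.322	8.687
"gene00007"	7.468	7.477	7.442	8.563	9.204	8.762	8.714	8.66	8.978	11.34	11.89	11.75	7.311	6.985	7.138	8.539	9.082	9.142	8.885	9.133	8.81	11.88	11.54	11.73
"gene00008"	6.628	7.02	7.234	8.531	8.587	8.226	8.356	8.755	8.627	11.17	11.39	11.65	7.21	6.826	7.426	8.527	8.494	8.341	8.573	8.452	8.609	11.2	11.37	11.64
"gene00009"	8.091	8.487	7.844	9.744	9.699	9.282	9.529	9.178	9.462	9.61	9.917	9.927	7.922	8.253	7.932	9.662	10.02	9.788	9.743	9.62	9.661	9.603	10.06	9.389
"gene00010"	7.487	7.537	7.369	8.691	9.144	8.876	9.159	9.17	8.998	9.08	9.32	9.459	7.447	7.609	7.322	8.931	8.978	8.744	9.063	9.115	9.075	8.996	8.993	8.939
"gene00011"	7.668	7.465	7.419	7.74	7.703	7.859	10.51	10.6	10.45	12.18	12.07	11.88	7.487	7.816	7.562	7.711	7.596	7.59	10.61	10.85	10.7	12.13	12.35	12.12
"gene00012"	6.733	7.404	7.266	7.427	7.708	7.299	10.09	10.21	9.672	11.37	12.24	11.66	6.801	6.501	7.379	6.393	6.727	6.78	10.01	10.15	9.732	11.13	11.86	11.56
"gene00013"	7.126	7.621	7.924	10.8	11.03	10.9	7.753	8.059	7.54	11.86	12.45	12.25	7.951	8.017	8.14	10.72	11.05	10.5	7.971	7.987	7.539	12.2	12.11	12.37
"gene00014"	7.778	7.593	7.526	10.53	10.79	10.65	7.726	7.807	7.725	12.39	12.33	12.19	7.502	7.691	7.919	10.68	11.03	10.85	7.744	7.878	7.73	12.27	12.4	12.31
"gene00015"	5.388	5.419	5.644	5.565	5.496	5.459	8.356	8.545	8.296	6.959	6.966	6.782	5.513	5.427	5.489	5.357	5.365	5.397	8.45	8.613	8.421	6.95	6.499	7.074
"gene00016"	9.262	9.155	9.362	9.526	9.364	9.459	12.27	12.39	12.46	10.76	10.91	10.8	9.198	9.18	9.519	9.005	9.504	9.382	12.21	12.46	12.4	10.89	11.05	11
"gene00017"	8.668	8.811	8.746	11.78	11.43	11.34	8.499	8.702	8.754	10.08	10.12	10.05	8.475	8.448	8.778	11.55	11.84	11.52	8.498	8.625	8.697	9.95	10	10.09
"gene00018"	7.984	8.135	8.226	11.28	10.97	11.29	8.274	8.148	8.106	9.473	9.955	9.807	8.224	8.313	8.251	11.31	11.38	11.14	8.269	7.987	8.332	9.682	9.543	10.01
"gene00019"	7.329	7.245	7.014	7.202	7.004	7.508	7.25	7.674	6.986	10.97	10.2	9.813	7.807	7.287	7.308	7.079	6.961	7.357	7.035	7.048	7.542	10.56	10.11	10.11
"gene00020"	8.372	8.517	8.403	8.657	8.581	8.289	8.287	8.965	8.353	12	11.61	11.6	8.912	8.609	8.444	8.685	8.654	8.584	8.856	9.01	8.625	11.69	11.61	11.62
"gene00021"	7.159	7.774	7.567	7.675	8.367	7.599	7.69	7.831	7.292	7.763	7.816	7.662	7.364	7.533	7.094	7.756	7.502	7.725	7.944	7.415	7.413	7.523	7.628	7.192
"gene00022"	7.862	8.373	7.996	7.714	7.331	7.523	8.002	7.554	7.299	7.993	7.073	7.589	7.887	8.082	7.828	7.642	7.135	7.779	7.386	7.817	7.491	7.518	8.23	7.951
"gene00023"	6.924	6.938	6.136	5.995	7.233	5.936	6.561	5.857	6.438	6.143	5.707	6.59	6.632	7.309	6.905	6.033	5.573	7.829	6.113	6.241	6.925	7.012	6.145	6.968
"gene00024"	9.533	9.711	9.638	9.39	9.248	9.45	9.54	9.52	9.638	9.507	9.478	9.523	9.276	9.639	9.501	9.643	9.732	9.448	9.081	9.543	9.378	9.549	9.329	9.306
"gene00025"	7.372	8.114	8.18	8.375	8.282	8.283	8.384	8.129	7.882	8.43	8.755	7.996	7.804	8.362	8.086	7.92	7.825	7.942	8.88	8.029	7.851	7.788	8.271	8.482
!series_matrix_table_end
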