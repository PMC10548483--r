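gene	B.cells	Macrophages.M1	Macrophages.M2	Monocytes	Neutrophils	NK.cells	T.cells.CD4	T.cells.CD8	Tregs	Dendritic.cells
G001	50.920417	0.733512	1.289866	1.466819	1.781724	0.73504	1.019159	0.936145	0.14313	0.918759
G002	54.170913	0.758822	0.5126	0.715763	1.082511	0.458025	0.944682	1.195039	1.075155	0.854025
G003	81.564836	0.857122	0.511478	1.579738	1.718669	0.612461	0.214733	0.239969	1.29838	1.424218
G004	104.889663	1.590916	0.838996	0.849438	0.941313	1.108414	0.722261	0.412792	0.895666	1.352707
G005	1.319316	49.228961	1.890666	1.389326	0.399972	0.140755	1.769015	1.505792	1.770605	0.873966
G006	1.086282	111.473743	1.928955	1.574068	0.940417	1.617645	1.868149	1.003851	0.305175	0.683148
G007	1.499518	86.02823	1.505725	0.456951	1.938694	0.309637	0.845139	1.40249	1.96253	0.584704
G008	0.355867	51.725792	1.493167	0.155263	1.020717	1.125617	0.401809	1.907878	0.603437	1.377879
G009	1.348285	0.596067	112.224464	0.357856	0.579671	1.185344	0.7079	1.045183	0.260127	1.799348
G010	1.439623	1.077385	60.240198	1.392312	0.593411	1.276008	0.683235	0.993951	0.833224	1.706899
G011	0.969709	1.383654	52.047808	1.876164	1.12983	1.458222	0.304841	1.164365	0.337302	0.846514
G012	1.466313	1.967353	101.483773	1.145939	1.334764	0.334271	1.960735	1.339769	1.204953	0.250196
G013	1.875877	1.543134	1.527893	58.409866	0.739196	0.690994	1.044117	0.63119	0.556284	1.674004
G014	0.585315	1.176328	0.96019	64.431946	0.215805	1.896904	0.276842	1.961824	1.471587	0.238494
G015	0.978356	1.71441	1.118001	81.485569	0.957491	1.050048	0.50237	1.323342	0.377265	0.318049
G016	1.886028	0.46	1.121016	66.767973	1.693635	0.356938	1.867951	1.206899	0.390394	1.31597
G017	1.95863	0.615445	0.102624	0.958584	52.354797	1.75159	0.664008	1.270155	0.592523	0.709076
G018	0.323226	1.673501	0.775765	0.702401	61.309565	0.489594	1.341115	1.857767	1.577984	0.458624
G019	1.002494	1.417089	1.263053	0.320732	68.060369	1.857587	1.812034	0.841044	0.910286	0.848276
G020	1.164632	0.557035	1.67499	0.453594	86.27667	1.784832	1.982512	0.647047	0.214092	1.737849
G021	1.81766	0.181679	0.777772	1.486487	1.030982	104.688144	0.917633	0.272398	0.318182	0.761032
G022	0.363549	0.36691	0.880207	0.882557	0.426101	114.661625	0.848176	0.711864	1.017238	0.102724
G023	1.978894	0.511132	1.189604	0.886694	1.131759	106.709067	0.369627	1.540713	1.96043	1.83144
G024	1.89867	1.010857	1.220389	1.012589	1.926789	50.160222	0.631633	0.298385	1.641882	1.908275
G025	0.256631	0.47508	1.467349	0.912239	0.695999	1.78192	91.956316	1.449528	1.131534	1.032746
G026	1.077002	1.466776	0.850449	0.359332	1.658978	0.739756	95.228133	1.936307	0.237497	0.980938
G027	0.841387	0.114981	1.846487	1.666891	0.683403	0.706621	42.563586	0.482833	0.986322	1.233297
G028	1.820902	0.813431	1.928884	1.225378	0.452362	0.867187	113.639132	0.306128	0.745821	1.821497
G029	0.949242	1.077375	0.543695	1.609354	0.191859	1.010247	1.472578	78.277511	1.410845	0.428702
G030	1.688408	0.102984	1.476545	1.561162	0.566781	0.799013	1.526398	61.321646	1.076899	1.593174
G031	1.501432	1.205048	1.816906	1.844307	0.767103	0.984812	1.855578	108.520857	1.078354	0.542575
G032	1.641005	0.40002	1.246601	1.738997	0.402143	0.194795	0.104518	58.331718	1.136477	1.196392
G033	0.837406	0.782154	1.299864	0.702253	0.677786	0.455978	0.404817	0.793527	103.35575	1.697666
G034	1.401822	1.326701	1.881033	0.592595	0.133342	1.967053	0.858619	0.632237	91.741989	0.351187
G035	0.107502	1.574064	1.715917	1.510306	1.99345	0.723721	1.383107	1.23946	73.946775	1.802193
G036	1.682541	1.170929	1.20166	1.519986	1.628347	0.424893	1.012707	1.655282	47.605461	0.955261
G037	0.113935	0.544036	1.660667	1.844018	0.264503	1.027684	1.114275	0.285881	0.886776	40.277416
G038	0.494552	0.270963	0.316065	1.607063	1.752873	0.135506	0.702205	1.93101	0.531255	82.490694
G039	1.822543	0.262663	1.552565	0.353326	1.153713	0.745022	1.648039	0.420599	0.289317	81.944569
G040	1.262379	0.679915	1.284866	0.646725	0.900619	0.15636	0.655217	0.263558	1.017555	57.054844
G041	0.821163	1.36811	0.382049	0.469885	0.22851	1.747734	0.877351	1.7363	1.335244	1.96165
G042	0.927966	0.100454	0.252502	1.589808	1.166732	1.490244	0.272745	1.097102	1.850527	1.019919
G043	0.171119	0.496283	0.981732	0.344857	0.234372	0.698996	1.617334	1.347941	0.788943	1.706247
G044	1.949726	1.872765	1.5808	0.34527	0.501645	0.834263	0.783592	0.536087	1.724756	0.890958
G045	0.920327	1.858725	1.493703	0.237281	1.144279	0.731647	0.176926	1.470329	0.671722	1.029751
G046	1.919396	1.494779	1.652738	0.200946	1.015765	0.270578	0.178064	1.032426	0.984759	0.448247
G047	1.786734	0.732837	0.423309	1.110561	0.402993	1.538406	1.913425	1.933986	0.371188	1.542407
G048	1.31596	1.07862	1.894969	0.313386	0.3842	1.24564	0.809348	1.823191	1.634666	0.679772
G049	1.944837	1.513552	0.657885	1.512057	1.048618	0.37626	1.632197	1.147376	1.365035	0.414789
G050	1.275793	1.276403	0.383237	1.489499	1.887073	0.161783	1.829112	0.243638	0.217688	0.162337
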