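cell_id	pair_id	homolog_id	short_um	long_um	sat_um	sat_arm
cell01	1	1	2.1411383532650627	2.2763748637987016	0	none
cell01	1	2	2.0803191238130165	2.346838985668457	0	none
cell01	2	1	1.845801936558147	1.9602054748255295	0	none
cell01	2	2	1.9766823985795092	2.104919989380106	0	none
cell01	3	1	1.8253006536637615	2.071731186184718	0	none
cell01	3	2	1.7574835356178842	1.8066044552243445	0	none
cell01	4	1	1.572034057026004	1.8959687309291386	0	none
cell01	4	2	1.4881185217097959	1.7740284969846059	0	none
cell01	5	1	1.3895812414257014	1.7929992759437874	0	none
cell01	5	2	1.3518728571971927	1.7769494656391753	0	none
cell01	6	1	1.4023761661234024	1.854950192808599	0	none
cell01	6	2	1.4280649146887936	1.7036101252605806	0	none
cell01	7	1	1.2991324910953934	1.710096059975513	0	none
cell01	7	2	1.0870229090923522	1.7056358863026861	0	none
cell01	8	1	1.1901756783587356	1.5737291296707567	0	none
cell01	8	2	1.1445756134096647	1.5673324736631615	0	none
cell01	9	1	1.1507792295753485	1.5860253320566486	0	none
cell01	9	2	1.0381990426080077	1.4862116955804308	0	none
cell01	10	1	0.956019046437866	1.495451961714432	0	none
cell01	10	2	1.1190684581702695	1.5332906521084138	0	none
cell01	11	1	1.0105182303723785	1.5917450443761867	0	none
cell01	11	2	1.0479016840192619	1.3585878368725026	0	none
cell02	1	1	2.0376745773061566	2.2597322772927404	0	none
cell02	1	2	2.072495828295422	1.9833794949928427	0	none
cell02	2	1	1.845833313960224	2.1471994199194655	0	none
cell02	2	2	1.9698613066692954	1.910300811291879	0	none
cell02	3	1	1.5950541491267278	1.9472247304775006	0	none
cell02	3	2	1.5783116116303166	1.9258783831894042	0	none
cell02	4	1	1.4679305527868138	1.8449452744947552	0	none
cell02	4	2	1.4402600421878062	1.7986197053080837	0	none
cell02	5	1	1.361328934589576	1.8750148256144294	0	none
cell02	5	2	1.3110773992944054	1.8071456512478323	0	none
cell02	6	1	1.372911344348994	1.5891870705219695	0	none
cell02	6	2	1.2972429720815402	1.6751733430621583	0	none
cell02	7	1	1.289808541099265	1.5104540037855285	0	none
cell02	7	2	1.2249209819508038	1.6889279050445487	0	none
cell02	8	1	1.244270618719556	1.6136798239847263	0	none
cell02	8	2	1.199536095655078	1.415734849751966	0	none
cell02	9	1	1.1074880980559456	1.4988708459382378	0	none
cell02	9	2	1.08757408630788	1.5726237036866013	0	none
cell02	10	1	1.0999084179622778	1.4204602891802345	0	none
cell02	10	2	1.0065644552313828	1.4153282517770653	0	none
cell02	11	1	0.862797818812939	1.3650111328492287	0	none
cell02	11	2	0.9879212394833825	1.4398042268601943	0	none
cell03	1	1	1.8248010679440017	2.0572775002310744	0	none
cell03	1	2	1.8081470406935203	1.9969023520326716	0	none
cell03	2	1	1.728927431831983	1.7303473801525973	0	none
cell03	2	2	1.7168880350395404	2.085406248136089	0	none
cell03	3	1	1.382009842657974	1.8408919026617878	0	none
cell03	3	2	1.445582655453625	1.7692212566980656	0	none
cell03	4	1	1.3356153445823404	1.7862643105381992	0	none
cell03	4	2	1.4145773632439704	1.684623773433225	0	none
cell03	5	1	1.393996598835531	1.605327810865382	0	none
cell03	5	2	1.4696126712126005	1.5289832403263772	0	none
cell03	6	1	1.2539886772648208	1.5487131697399168	0	none
cell03	6	2	1.2923499835874093	1.509431194643734	0	none
cell03	7	1	1.153654141523204	1.503991855035658	0	none
cell03	7	2	1.0761948328903177	1.4233886465625925	0	none
cell03	8	1	1.0939640822331615	1.3674395302897424	0	none
cell03	8	2	1.063034242104798	1.4036315496408516	0	none
cell03	9	1	1.0672076674626654	1.4267336417558774	0	none
cell03	9	2	0.9794880104578894	1.3243840749492906	0	none
cell03	10	1	0.8942952856766929	1.3484211039467964	0	none
cell03	10	2	0.8873683744380799	1.2966668958842347	0	none
cell03	11	1	0.9422291360629346	1.2939333122386882	0	none
cell03	11	2	0.8600709064460302	1.4054237502889457	0	none
cell04	1	1	1.798087845672334	2.0267441242733963	0	none
cell04	1	2	1.9603290372584241	2.131100204834345	0	none
cell04	2	1	1.730926031258442	2.1083064820629906	0	none
cell04	2	2	1.6776154808869153	1.9325950456816579	0	none
cell04	3	1	1.6056768912738206	1.8271482129158987	0	none
cell04	3	2	1.4676894377296579	1.975912634197811	0	none
cell04	4	1	1.387812486233365	1.707435769413681	0	none
cell04	4	2	1.5756054759050309	1.686038306651685	0	none
cell04	5	1	1.4007657186916607	1.6749804412471438	0	none
cell04	5	2	1.3914979141439825	1.5261420235749508	0	none
cell04	6	1	1.3637651918395148	1.694857256339926	0	none
cell04	6	2	1.2591787952062956	1.779308605530983	0	none
cell04	7	1	1.2207175937686583	1.503018898183529	0	none
cell04	7	2	1.2316353931910609	1.6034490869405316	0	none
cell04	8	1	1.0340403736938353	1.4365518036886322	0	none
cell04	8	2	1.0921287434900733	1.4874681032104757	0	none
cell04	9	1	1.1573732460366164	1.4456060519223874	0	none
cell04	9	2	1.0927903209101544	1.5014037136937495	0	none
cell04	10	1	0.9286763938857763	1.452867365841369	0	none
cell04	10	2	0.8326500304142762	1.3767995284875987	0	none
cell04	11	1	0.9230684465522039	1.3645143056612277	0	none
cell04	11	2	0.8942390785165933	1.2919485389958298	0	none
cell05	1	1	2.088243555917205	2.2914246216426193	0	none
cell05	1	2	2.132046315597168	2.3869265619452467	0	none
cell05	2	1	1.7789328778037476	1.9845575770842516	0	none
cell05	2	2	1.8048633521856268	2.0103224160342723	0	none
cell05	3	1	1.7514440897776313	1.9878641014760816	0	none
cell05	3	2	1.772956572948809	2.062370513618794	0	none
cell05	4	1	1.5317314503632269	1.9202144460381592	0	none
cell05	4	2	1.5082056189501458	1.815492009186527	0	none
cell05	5	1	1.4838340076030492	1.8474023925551413	0	none
cell05	5	2	1.4067806815884176	1.7465790158239252	0	none
cell05	6	1	1.281705521053103	1.5013087878233766	0	none
cell05	6	2	1.3884265219382967	1.7779866393004664	0	none
cell05	7	1	1.3310687657328777	1.6866012012418747	0	none
cell05	7	2	1.3459251974060171	1.7120309309252126	0	none
cell05	8	1	1.2169429777417946	1.6318053425858308	0	none
cell05	8	2	1.2590450383434557	1.5430683889809833	0	none
cell05	9	1	1.1363630392971964	1.61519888037188	0	none
cell05	9	2	1.2438148606805826	1.4813113937561802	0	none
cell05	10	1	0.9518161240425205	1.5889520013610055	0	none
cell05	10	2	1.0421931868039815	1.4844779587225265	0	none
cell05	11	1	1.0041344801418814	1.4166042084721404	0	none
cell05	11	2	0.9431874098035842	1.4236856509900888	0	none
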