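"taxon","wbf_hz","mass_mg","in_europe","obs_prob"
"taxon_001",57.8010942684487,7.49225435987848,TRUE,1
"taxon_002",197.846091396874,4.84181340460067,TRUE,1
"taxon_003",105.302374951076,11.7467474030521,FALSE,1
"taxon_004",92.7738154591061,2.03049659875657,TRUE,1
"taxon_005",152.86004777276,8.38717765631149,TRUE,1
"taxon_006",153.362297834828,6.16422863179826,TRUE,1
"taxon_007",48.2947242886294,60.387923095105,TRUE,1
"taxon_008",85.517602409469,50.5281572913854,TRUE,1
"taxon_009",147.496572263539,13.7571134505877,TRUE,1
"taxon_010",159.184461093508,3.83401073045921,TRUE,1
"taxon_011",133.131481562974,44.2033189610646,FALSE,1
"taxon_012",131.600237200269,41.6863917082327,TRUE,1
"taxon_013",137.953742406797,35.9205088698013,TRUE,1
"taxon_014",143.037626415957,36.3012717803539,FALSE,1
"taxon_015",211.074367794441,9.83054780782323,TRUE,1
"taxon_016",202.706203836249,34.9762345250337,TRUE,1
"taxon_017",45.407364593586,71.412990143527,FALSE,1
"taxon_018",175.107750596479,15.7045835887762,TRUE,1
"taxon_019",217.54992989637,4.63163379390117,TRUE,1
"taxon_020",82.2614292721264,38.8832543360863,TRUE,1
"taxon_021",70.9762120011728,38.5462356800879,TRUE,1
"taxon_022",24.3572464606259,10.3345685312038,TRUE,1
"taxon_023",49.2469613347203,115.204869320212,TRUE,1
"taxon_024",41.450642344309,5.78077496590575,FALSE,1
"taxon_025",72.8778166361153,22.7866641815293,TRUE,1
"taxon_026",194.261282674503,0.98962312799883,TRUE,1
"taxon_027",152.341212885221,12.3468857621669,TRUE,1
"taxon_028",220.322348695016,58.2700471811153,TRUE,1
"taxon_029",143.732977310428,8.68324259348118,TRUE,1
"taxon_030",186.499344447395,5.09903151386798,TRUE,1
"taxon_031",104.038644159213,35.8827573400333,TRUE,1
"taxon_032",102.748533940874,5.67869310359659,TRUE,1
"taxon_033",58.2936507915147,20.6672917161297,TRUE,1
"taxon_034",120.274303873535,1.86513558178584,TRUE,1
"taxon_035",77.5926573404577,2.75754292354058,TRUE,1
"taxon_036",94.6422435594723,8.70405256234774,TRUE,1
"taxon_037",215.818684593542,4.32953727176442,FALSE,1
"taxon_038",65.2262394425925,76.9089052665743,TRUE,1
"taxon_039",147.841743366793,45.1052336609069,TRUE,1
"taxon_040",66.4714145469479,5.84671291125883,TRUE,1
"taxon_041",311.68558798891,6.62606528833021,TRUE,1
"taxon_042",322.218982557887,12.7931234757622,FALSE,1
"taxon_043",322.074371936629,3.40335194517373,TRUE,1
"taxon_044",259.995255235579,3.57646232591723,TRUE,1
"taxon_045",300.113947934011,10.7352010005826,TRUE,1
"taxon_046",282.984170358564,1.78288461652271,TRUE,1
"taxon_047",480,2.64694346921474,FALSE,1
"taxon_048",641.272153318537,3.69753279504723,FALSE,1
"taxon_049",613.003300416599,2.34799612564995,TRUE,1
"taxon_050",518.76955705795,2.29846806489025,TRUE,1
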