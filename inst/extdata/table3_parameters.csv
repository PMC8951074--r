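parameter,hybrid_agrigreen,landrace_kantana,improved_kangara
k_par,0.43,0.40,0.42
k_s,0.31,0.28,0.30
rue_kg_mj,0.0019,0.0026,0.002
dwr_pa,11.3,15.8,11.2
wue_grain_kg_m3,1.43,1.29,1.23
wue_biomass_kg_m3,4.83,9.16,4.69
sla_m2_kg,22.49,19.91,23.34
partition_p_m2_kg,2.76,1.27,2.48
rd_max_m,1.00,1.00,1.00
h_max_m,2.87,4.22,2.80
t_max_rate_mm_d,9,9,9
t_base_c,10,10,10
t_opt_c,33,33,33
t_cutoff_c,45,45,45
gdd_emerge,60,64,60
gdd_flower,900,1058,832
gdd_maturity,1686,2124,1480
gdd_transition,670,780,655
dm_at_emergence_kg_m2,0.0019,0.0019,0.0019
stress_index,0.30,0.30,0.30
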