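# Landrace pearl millet (Kantana) - measured growth parameters
name = "kantana"
rue = 0.0026            # radiation use efficiency, kg MJ-1
dwr = 15.8              # dry matter / transpiration ratio, Pa
k_par = 0.40            # canopy extinction coefficient for PAR
a_p = 0.8               # leaf absorptance of PAR
a_n = 0.2               # leaf absorptance of NIR
sla = 19.91             # specific leaf area, m2 kg-1
p = 1.27                # leaf-stem partition parameter, m2 kg-1
rd_max = 1.00           # maximum root depth, m
h_max = 4.22            # maximum crop height, m
t_max_rate = 9          # maximum transpiration rate, mm d-1
t_base = 10
t_opt = 33
t_cutoff = 45
gdd_emerge = 64
gdd_transition = 780
gdd_flower = 1058
gdd_maturity = 2124
dm_at_emergence = 0.0019
stress_threshold = 0.30
root_fraction_initial = 0.25
vpd_floor = 100
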