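name,lower,upper,baseline,units,submodel
k_epi,0,1000000,200000,Ba/cm,robin_epicardium
P0,7.5,30,20,mmHg,windkessel
P_ej,33.75,135,67.5,mmHg,windkessel
C,0.1,0.4,0.2,ml/mmHg,windkessel
R,75,750,750,mmHg ms/ml,windkessel
kort2,0,0.6,0,dimensionless,orthotropic_activation
T_ref,60,1200,120,kPa,active_stress
phi,45,90,60,deg,fibre_distribution
K,500,5000,3333,kPa,passive_stress
a_s,512.8,7692,2564,Pa,passive_stress
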