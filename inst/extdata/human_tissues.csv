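# Per-tissue physiology table, human (70 kg).
# Default configuration values compiled from standard antibody-PBPK
# physiology tables; editable configuration, not algorithm.
# Endosomal volumes taken as 1% of total tissue volume; lymph flows as
# 0.2% of plasma flow. Units: volumes L, flows L/h.
tissue,V_v_L,V_e_L,V_is_L,Q_L_per_h,L_L_per_h
brain,0.0145,0.0145,0.261,21.0,0.0420
muscle,0.4418,0.2945,3.829,45.0,0.0900
skin,0.0682,0.0341,1.023,17.0,0.0340
adipose,0.1347,0.1347,1.818,14.0,0.0280
lung,0.3042,0.0117,0.222,5.0,0.0100
heart,0.0171,0.0034,0.0341,12.9,0.0258
kidney,0.0266,0.0033,0.0664,40.0,0.0800
bone,0.3300,0.1100,1.100,9.0,0.0180
small_intestine,0.0193,0.0039,0.0770,21.0,0.0420
large_intestine,0.0274,0.0055,0.1096,13.0,0.0260
spleen,0.0376,0.0022,0.0332,9.0,0.0180
liver,0.1859,0.0169,0.3380,14.0,0.0280
pancreas,0.0052,0.0010,0.0125,3.0,0.0060
thymus,0.0015,0.0003,0.0044,0.7,0.0014
other,0.1200,0.0300,0.4500,9.0,0.0180
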