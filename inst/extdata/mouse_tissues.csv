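# Per-tissue physiology table, mouse (28 g).
# Default configuration values compiled from standard antibody-PBPK
# physiology tables (tissue volumes and plasma flows of the whole-body
# antibody PBPK literature); editable configuration, not algorithm.
# Vascular volumes are residual plasma in tissue; endosomal volumes are
# taken as 1% of total tissue volume; lymph flows as 0.2% of plasma flow.
# Units: volumes L, flows L/h.
tissue,V_v_L,V_e_L,V_is_L,Q_L_per_h,L_L_per_h
brain,4.85e-6,4.85e-6,8.73e-5,0.0140,2.80e-5
muscle,1.695e-4,1.13e-4,1.469e-3,0.0910,1.82e-4
skin,1.004e-4,5.02e-5,1.506e-3,0.0300,6.00e-5
adipose,1.98e-5,1.98e-5,2.67e-4,0.0150,3.00e-5
lung,5.30e-5,2.04e-6,3.88e-5,0.0100,2.00e-5
heart,7.60e-6,1.52e-6,1.52e-5,0.0280,5.60e-5
kidney,4.20e-5,5.25e-6,1.05e-4,0.0800,1.60e-4
bone,8.46e-5,2.82e-5,2.82e-4,0.0150,3.00e-5
small_intestine,3.64e-5,7.28e-6,1.456e-4,0.0430,8.60e-5
large_intestine,1.57e-5,3.14e-6,6.28e-5,0.0170,3.40e-5
spleen,2.16e-5,1.27e-6,1.90e-5,0.0090,1.80e-5
liver,2.123e-4,1.93e-5,3.86e-4,0.0130,2.60e-5
pancreas,4.85e-6,9.70e-7,1.16e-5,0.0060,1.20e-5
thymus,4.50e-7,9.00e-8,1.35e-6,0.0010,2.00e-6
other,1.86e-5,4.65e-6,6.98e-5,0.0080,1.60e-5
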