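muscle,printed_name,printed_force,force_N,ambiguous
adductor_brevis,Adductor brevis,0.00,0.00,FALSE
adductor_longus,Adductor longus,0.00,0.00,FALSE
adductor_magnus_1,Adductor magnus 1,0.00,0.00,FALSE
adductor_magnus_2,Adductor magnus 2,0.00,0.00,FALSE
adductor_magnus_3,Adductor magnus 3,0.00,0.00,FALSE
biceps_femoris_long,Biceps femoris - long head,0.02,0.02,FALSE
biceps_femoris_short,Biceps femoris - short head,33.2,33.2,FALSE
gluteus_maximus_1,Gluteus maximus 1,47.8,47.8,FALSE
gluteus_maximus_2,Gluteus maximus 2,27.IV,27.4,TRUE
gluteus_maximus_3,Gluteus maximus 3,0.00,0.00,FALSE
gluteus_medius_1,Gluteus medius 1,620.6,620.6,FALSE
gluteus_medius_2,Gluteus medius 2,251.6,251.6,FALSE
gluteus_medius_3,Gluteus medius 3,197.9,197.9,FALSE
gluteus_minimus_1,Gluteus minimus 1,71.5,71.5,FALSE
gluteus_minimus_2,Gluteus minimus 2,76.4,76.4,FALSE
gluteus_minimus_3,Gluteus minimus 3,77.5,77.5,FALSE
gracilis,Gracilis,0.00,0.00,FALSE
iliacus,Iliacue,37.2,37.2,TRUE
pectineus,Pectineus,0.00,0.00,FALSE
piriformis,Piriformis,0.02,0.02,FALSE
psoas_major,Psoas major,52.8,52.8,FALSE
quadratus_femoris,Quadratus femoris,0.00,0.00,FALSE
rectus_femoris,Rectus femoris,43.5,43.5,FALSE
sartorius,Sartorius,13.I,13.1,TRUE
semimembranosus,Semimembranosus,0.03,0.03,FALSE
semitendinosus,Semitendinosus,0.01,0.01,FALSE
tensor_fasciae_latae,Tensor fasciae latae,81.8,81.8,FALSE
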