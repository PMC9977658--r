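view,kvp_min,kvp_max,mas_3_7,mas_8_15,mas_16_25,mas_26_40,mas_41_60,mas_60plus,grid,sid_cm
Chest AP/PA,70,90,0.71,0.8,1,1.2,1.4,2,FALSE,125
Chest Lateral,70,100,1,1.6,2,2.5,3.2,4,FALSE,125
Sternum Lateral,65,75,4,6,12,16,20,32,FALSE,100
Chest AP for Ribs,65,70,4,4.5,8,12,14,20,FALSE,100
Ribs Bilateral Oblique,65,70,4,4.5,8,12,14,20,FALSE,100
Abdomen AP,60,70,0.8,1,2,8,16,25,FALSE,100
Abdomen AP (including pelvis),70,75,4,5,8,10,14,25,FALSE,100
Shoulder AP,55,65,1,1.4,2,4,10,14,FALSE,100
Shoulder Lateral,60,70,1.6,2,3,4,14,18,FALSE,100
Humerus AP,55,65,1.2,1.4,1.6,2,2.5,3,FALSE,100
Forearm AP,52,55,1,1.4,1.6,2,2.5,3,FALSE,100
Hands AP,50,55,1,1.2,1.2,1.4,1.6,2,FALSE,100
Pelvis AP,70,75,1.4,1.6,2,8,10,20,FALSE,100
Femur Bilateral AP,55,65,1,1.4,1.6,2,8,10,FALSE,100
Knee AP/Lateral,55,65,1,1.2,1.4,2,2.4,3.2,FALSE,100
Tibia/Fibula AP/Lateral (including bilateral),55,65,1,1.2,1.4,2,2.4,3.2,FALSE,100
Ankle AP/Mortise/Lateral,55,55,1,1.2,1.2,1.6,2,3,FALSE,100
Foot AP/Oblique/Lateral,50,55,0.8,1,1,1.4,1.6,2,FALSE,100
Cervical Spine AP/Odontoid,65,75,2,2.5,3,4,5,10,FALSE,100
Cervical Spine Lateral,65,75,2,2.5,3,4,5,10,FALSE,100
Cervical Spine Swimmers,77,85,,,,20,30,40,FALSE,100
Thoracic Spine AP,65,70,4,4.5,8,12,14,20,FALSE,100
Thoracic Spine Lateral,65,75,4,6,12,16,20,32,FALSE,100
Thoracic Spine Breathing Lateral,70,75,,,,120,140,160,FALSE,100
Lateral Spine AP,70,75,4,5,8,10,14,25,FALSE,100
Lateral Spine Lateral,72,85,4,6,12,14,20,40,FALSE,100
Skull AP/Lateral/Townes,65,75,6,8,10,12,14,16,FALSE,100
Skull SMV,65,75,8,10,12,14,16,18,FALSE,100
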