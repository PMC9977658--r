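exam,band,effective_dose_mSv,provenance,below_threshold,published_one_in_n,published_category
"Chest AP",3-7,0.007,monte_carlo,FALSE,283000,Minimal
"Chest AP",8-15,0.008,monte_carlo,FALSE,275000,Minimal
"Chest AP",16-25,0.014,monte_carlo,FALSE,216000,Minimal
"Chest AP",26-40,0.022,monte_carlo,FALSE,171000,Minimal
"Chest AP",41-60,0.024,monte_carlo,FALSE,208000,Minimal
"Chest AP",60+,0.033,monte_carlo,FALSE,166000,Minimal
"Chest Lateral",3-7,0.007,monte_carlo,FALSE,317000,Minimal
"Chest Lateral",8-15,0.012,monte_carlo,FALSE,193000,Minimal
"Chest Lateral",16-25,0.017,monte_carlo,FALSE,178000,Minimal
"Chest Lateral",26-40,0.027,monte_carlo,FALSE,133000,Minimal
"Chest Lateral",41-60,0.038,monte_carlo,FALSE,105000,Minimal
"Chest Lateral",60+,0.047,monte_carlo,FALSE,116000,Minimal
"Abdomen AP",3-7,0.010,monte_carlo,FALSE,201000,Minimal
"Abdomen AP",8-15,0.013,monte_carlo,FALSE,167000,Minimal
"Abdomen AP",16-25,0.030,monte_carlo,FALSE,99700,Very Low
"Abdomen AP",26-40,0.130,monte_carlo,FALSE,29600,Very Low
"Abdomen AP",41-60,0.178,monte_carlo,FALSE,26900,Very Low
"Abdomen AP",60+,0.286,monte_carlo,FALSE,19300,Very Low
"Shoulder AP",3-7,0.003,monte_carlo,FALSE,748000,Minimal
"Shoulder AP",8-15,0.004,monte_carlo,FALSE,570000,Minimal
"Shoulder AP",16-25,0.006,monte_carlo,FALSE,494000,Minimal
"Shoulder AP",26-40,0.015,monte_carlo,FALSE,261000,Minimal
"Shoulder AP",41-60,0.021,monte_carlo,FALSE,238000,Minimal
"Shoulder AP",60+,0.028,monte_carlo,FALSE,201000,Minimal
"Shoulder Lateral",3-7,0.001,monte_carlo,FALSE,2326000,Negligible
"Shoulder Lateral",8-15,0.001,monte_carlo,FALSE,2780000,Negligible
"Shoulder Lateral",16-25,0.002,monte_carlo,FALSE,1742000,Negligible
"Shoulder Lateral",26-40,0.003,monte_carlo,FALSE,1292000,Negligible
"Shoulder Lateral",41-60,0.007,monte_carlo,FALSE,655000,Minimal
"Shoulder Lateral",60+,0.008,monte_carlo,FALSE,698000,Minimal
"Pelvis AP",3-7,0.011,monte_carlo,FALSE,182000,Minimal
"Pelvis AP",8-15,0.012,monte_carlo,FALSE,187000,Minimal
"Pelvis AP",16-25,0.015,monte_carlo,FALSE,192000,Minimal
"Pelvis AP",26-40,0.058,monte_carlo,FALSE,66500,Very Low
"Pelvis AP",41-60,0.065,monte_carlo,FALSE,74500,Very Low
"Pelvis AP",60+,0.124,monte_carlo,FALSE,44700,Very Low
"Knee AP and Lateral",3-7,0.001,monte_carlo,TRUE,10470000,Negligible
"Knee AP and Lateral",8-15,0.001,monte_carlo,TRUE,11120000,Negligible
"Knee AP and Lateral",16-25,0.001,monte_carlo,TRUE,13670000,Negligible
"Knee AP and Lateral",26-40,0.001,monte_carlo,TRUE,18090000,Negligible
"Knee AP and Lateral",41-60,0.001,monte_carlo,TRUE,20900000,Negligible
"Knee AP and Lateral",60+,0.001,monte_carlo,TRUE,43820000,Negligible
"Tibia/Fibula AP and Lateral",3-7,0.001,monte_carlo,TRUE,5233000,Negligible
"Tibia/Fibula AP and Lateral",8-15,0.001,monte_carlo,TRUE,5559000,Negligible
"Tibia/Fibula AP and Lateral",16-25,0.001,monte_carlo,TRUE,6836000,Negligible
"Tibia/Fibula AP and Lateral",26-40,0.001,monte_carlo,TRUE,6029000,Negligible
"Tibia/Fibula AP and Lateral",41-60,0.001,monte_carlo,TRUE,10450000,Negligible
"Tibia/Fibula AP and Lateral",60+,0.001,monte_carlo,TRUE,21910000,Negligible
"Ankle AP, Mortise and Lateral",3-7,0.001,monte_carlo,TRUE,20930000,Negligible
"Ankle AP, Mortise and Lateral",8-15,0.001,monte_carlo,TRUE,11120000,Negligible
"Ankle AP, Mortise and Lateral",16-25,0.001,monte_carlo,TRUE,27350000,Negligible
"Ankle AP, Mortise and Lateral",26-40,0.001,monte_carlo,TRUE,36180000,Negligible
"Ankle AP, Mortise and Lateral",41-60,0.001,monte_carlo,TRUE,87610000,Negligible
"Ankle AP, Mortise and Lateral",60+,0.001,monte_carlo,TRUE,125200000,Negligible
"Foot AP, Oblique and Lateral",3-7,0.001,monte_carlo,TRUE,20930000,Negligible
"Foot AP, Oblique and Lateral",8-15,0.001,monte_carlo,TRUE,11240000,Negligible
"Foot AP, Oblique and Lateral",16-25,0.001,monte_carlo,TRUE,74030000,Negligible
"Foot AP, Oblique and Lateral",26-40,0.001,monte_carlo,TRUE,90440000,Negligible
"Foot AP, Oblique and Lateral",41-60,0.001,monte_carlo,TRUE,219030000,Negligible
"Foot AP, Oblique and Lateral",60+,0.001,monte_carlo,TRUE,292140000,Negligible
"Cervical Spine AP and Lateral",3-7,0.011,monte_carlo,FALSE,174000,Minimal
"Cervical Spine AP and Lateral",8-15,0.014,monte_carlo,FALSE,148000,Minimal
"Cervical Spine AP, Odontoid and Lateral",16-25,0.021,monte_carlo,FALSE,137000,Minimal
"Cervical Spine AP, Odontoid and Lateral",26-40,0.026,monte_carlo,FALSE,147000,Minimal
"Cervical Spine AP, Odontoid and Lateral",41-60,0.034,monte_carlo,FALSE,127000,Minimal
"Cervical Spine AP, Odontoid and Lateral",60+,0.059,monte_carlo,FALSE,93500,Very Low
"Cervical Spine AP, Odontoid, Lateral and Swimmers",26-40,0.039,monte_carlo,FALSE,97800,Very Low
"Cervical Spine AP, Odontoid, Lateral and Swimmers",41-60,0.056,monte_carlo,FALSE,78900,Very Low
"Cervical Spine AP, Odontoid, Lateral and Swimmers",60+,0.091,monte_carlo,FALSE,60600,Very Low
"Thoracic Spine AP and Lateral",3-7,0.035,monte_carlo,FALSE,59800,Very Low
"Thoracic Spine AP and Lateral",8-15,0.041,monte_carlo,FALSE,54200,Very Low
"Thoracic Spine AP and Lateral",16-25,0.071,monte_carlo,FALSE,38000,Very Low
"Thoracic Spine AP and Lateral",26-40,0.103,monte_carlo,FALSE,35100,Very Low
"Thoracic Spine AP and Lateral",41-60,0.144,monte_carlo,FALSE,28800,Very Low
"Thoracic Spine AP and Lateral",60+,0.202,monte_carlo,FALSE,27300,Very Low
"Thoracic Spine AP and Breathing Lateral",26-40,0.317,monte_carlo,FALSE,11200,Very Low
"Thoracic Spine AP and Breathing Lateral",41-60,0.445,monte_carlo,FALSE,9400,Low
"Thoracic Spine AP and Breathing Lateral",60+,0.595,monte_carlo,FALSE,9300,Low
"Lumbar Spine AP and Lateral",3-7,0.050,monte_carlo,FALSE,41900,Very Low
"Lumbar Spine AP and Lateral",8-15,0.058,monte_carlo,FALSE,38300,Very Low
"Lumbar Spine AP and Lateral",16-25,0.094,monte_carlo,FALSE,27600,Very Low
"Lumbar Spine AP and Lateral",26-40,0.131,monte_carlo,FALSE,27200,Very Low
"Lumbar Spine AP and Lateral",41-60,0.183,monte_carlo,FALSE,22100,Very Low
"Lumbar Spine AP and Lateral",60+,0.326,monte_carlo,FALSE,16900,Very Low
"Skull AP and Lateral",3-7,0.025,monte_carlo,FALSE,83700,Very Low
"Skull AP and Lateral",8-15,0.025,monte_carlo,FALSE,89000,Very Low
"Skull AP and Lateral",16-25,0.026,monte_carlo,FALSE,105000,Minimal
"Skull AP and Lateral",26-40,0.026,monte_carlo,FALSE,139000,Minimal
"Skull AP and Lateral",41-60,0.028,monte_carlo,FALSE,149000,Minimal
"Skull AP and Lateral",60+,0.031,monte_carlo,FALSE,178000,Minimal
"Skull AP, Lateral, Townes and SMV",3-7,0.054,monte_carlo,FALSE,38800,Very Low
"Skull AP, Lateral, Townes and SMV",8-15,0.054,monte_carlo,FALSE,41200,Very Low
"Skull AP, Lateral, Townes and SMV",16-25,0.056,monte_carlo,FALSE,49700,Very Low
"Skull AP, Lateral, Townes and SMV",26-40,0.054,monte_carlo,FALSE,67000,Very Low
"Skull AP, Lateral, Townes and SMV",41-60,0.059,monte_carlo,FALSE,72100,Very Low
"Skull AP, Lateral, Townes and SMV",60+,0.066,monte_carlo,FALSE,83600,Very Low
"Skeletal Survey - Non-Accidental Injury",3-7,0.245,monte_carlo,FALSE,8400,Low
"Skeletal Survey - Non-Accidental Injury",8-15,0.272,monte_carlo,FALSE,8200,Low
"Skeletal Survey - Non-Accidental Injury",16-25,0.464,monte_carlo,FALSE,5600,Low
"Skeletal Survey - Non-Accidental Injury",26-40,0.724,monte_carlo,FALSE,4900,Low
"Skeletal Survey - Non-Accidental Injury",41-60,0.869,monte_carlo,FALSE,4600,Low
"Skeletal Survey - Non-Accidental Injury",60+,1.321,monte_carlo,FALSE,6500,Low
"Skeletal Survey - Bone Dysplasia",3-7,0.184,monte_carlo,FALSE,11600,Very Low
"Skeletal Survey - Bone Dysplasia",8-15,0.205,monte_carlo,FALSE,11100,Very Low
"Skeletal Survey - Bone Dysplasia",16-25,0.324,monte_carlo,FALSE,8000,Low
"Skeletal Survey - Bone Dysplasia",26-40,0.489,monte_carlo,FALSE,7400,Low
"Skeletal Survey - Bone Dysplasia",41-60,0.617,monte_carlo,FALSE,6700,Low
"Skeletal Survey - Bone Dysplasia",60+,0.960,monte_carlo,FALSE,9000,Low
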