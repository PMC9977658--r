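{
  "exams": [
    {"exam": "Chest AP",
     "views": [{"name": "Chest AP", "chart": "Chest AP/PA"}],
     "bands": null},
    {"exam": "Chest Lateral",
     "views": [{"name": "Chest Lateral", "chart": "Chest Lateral"}],
     "bands": null},
    {"exam": "Abdomen AP",
     "views": [{"name": "Abdomen AP", "chart": "Abdomen AP"}],
     "bands": null},
    {"exam": "Shoulder AP",
     "views": [{"name": "Shoulder AP", "chart": "Shoulder AP"}],
     "bands": null},
    {"exam": "Shoulder Lateral",
     "views": [{"name": "Shoulder Lateral", "chart": "Shoulder Lateral"}],
     "bands": null},
    {"exam": "Pelvis AP",
     "views": [{"name": "Pelvis AP", "chart": "Pelvis AP"}],
     "bands": null},
    {"exam": "Knee AP and Lateral",
     "views": [{"name": "Knee AP", "chart": "Knee AP/Lateral"},
               {"name": "Knee Lateral", "chart": "Knee AP/Lateral"}],
     "bands": null},
    {"exam": "Tibia/Fibula AP and Lateral",
     "views": [{"name": "Tibia/Fibula AP", "chart": "Tibia/Fibula AP/Lateral (including bilateral)"},
               {"name": "Tibia/Fibula Lateral", "chart": "Tibia/Fibula AP/Lateral (including bilateral)"}],
     "bands": null},
    {"exam": "Ankle AP, Mortise and Lateral",
     "views": [{"name": "Ankle AP", "chart": "Ankle AP/Mortise/Lateral"},
               {"name": "Ankle Mortise", "chart": "Ankle AP/Mortise/Lateral"},
               {"name": "Ankle Lateral", "chart": "Ankle AP/Mortise/Lateral"}],
     "bands": null},
    {"exam": "Foot AP, Oblique and Lateral",
     "views": [{"name": "Foot AP", "chart": "Foot AP/Oblique/Lateral"},
               {"name": "Foot Oblique", "chart": "Foot AP/Oblique/Lateral"},
               {"name": "Foot Lateral", "chart": "Foot AP/Oblique/Lateral"}],
     "bands": null},
    {"exam": "Cervical Spine AP and Lateral",
     "views": [{"name": "Cervical Spine AP", "chart": "Cervical Spine AP/Odontoid"},
               {"name": "Cervical Spine Lateral", "chart": "Cervical Spine Lateral"}],
     "bands": ["3-7", "8-15"]},
    {"exam": "Cervical Spine AP, Odontoid and Lateral",
     "views": [{"name": "Cervical Spine AP", "chart": "Cervical Spine AP/Odontoid"},
               {"name": "Cervical Spine Odontoid", "chart": "Cervical Spine AP/Odontoid"},
               {"name": "Cervical Spine Lateral", "chart": "Cervical Spine Lateral"}],
     "bands": ["16-25", "26-40", "41-60", "60+"]},
    {"exam": "Cervical Spine AP, Odontoid, Lateral and Swimmers",
     "views": [{"name": "Cervical Spine AP", "chart": "Cervical Spine AP/Odontoid"},
               {"name": "Cervical Spine Odontoid", "chart": "Cervical Spine AP/Odontoid"},
               {"name": "Cervical Spine Lateral", "chart": "Cervical Spine Lateral"},
               {"name": "Cervical Spine Swimmers", "chart": "Cervical Spine Swimmers"}],
     "bands": ["26-40", "41-60", "60+"]},
    {"exam": "Thoracic Spine AP and Lateral",
     "views": [{"name": "Thoracic Spine AP", "chart": "Thoracic Spine AP"},
               {"name": "Thoracic Spine Lateral", "chart": "Thoracic Spine Lateral"}],
     "bands": null},
    {"exam": "Thoracic Spine AP and Breathing Lateral",
     "views": [{"name": "Thoracic Spine AP", "chart": "Thoracic Spine AP"},
               {"name": "Thoracic Spine Breathing Lateral", "chart": "Thoracic Spine Breathing Lateral"}],
     "bands": ["26-40", "41-60", "60+"]},
    {"exam": "Lumbar Spine AP and Lateral",
     "views": [{"name": "Lumbar Spine AP", "chart": "Lateral Spine AP"},
               {"name": "Lumbar Spine Lateral", "chart": "Lateral Spine Lateral"}],
     "bands": null},
    {"exam": "Skull AP and Lateral",
     "views": [{"name": "Skull AP", "chart": "Skull AP/Lateral/Townes"},
               {"name": "Skull Lateral", "chart": "Skull AP/Lateral/Townes"}],
     "bands": null},
    {"exam": "Skull AP, Lateral, Townes and SMV",
     "views": [{"name": "Skull AP", "chart": "Skull AP/Lateral/Townes"},
               {"name": "Skull Lateral", "chart": "Skull AP/Lateral/Townes"},
               {"name": "Skull Townes", "chart": "Skull AP/Lateral/Townes"},
               {"name": "Skull SMV", "chart": "Skull SMV"}],
     "bands": null},
    {"exam": "Skeletal Survey - Non-Accidental Injury",
     "views": [{"name": "Skull AP", "chart": "Skull AP/Lateral/Townes"},
               {"name": "Skull Lateral", "chart": "Skull AP/Lateral/Townes"},
               {"name": "AP Chest (for ribs)", "chart": "Chest AP for Ribs"},
               {"name": "Oblique Ribs Bilateral", "chart": "Ribs Bilateral Oblique"},
               {"name": "AP Abdomen incl. Pelvis", "chart": "Abdomen AP (including pelvis)"},
               {"name": "Lateral Spine", "chart": "Lateral Spine Lateral"},
               {"name": "Lateral Sternum", "chart": "Sternum Lateral"},
               {"name": "Bilateral AP Femur", "chart": "Femur Bilateral AP"},
               {"name": "Bilateral AP Tibia/Fibula", "chart": "Tibia/Fibula AP/Lateral (including bilateral)"},
               {"name": "Bilateral Feet", "chart": "Foot AP/Oblique/Lateral"},
               {"name": "Bilateral AP Humeri", "chart": "Humerus AP"},
               {"name": "Bilateral AP Forearms", "chart": "Forearm AP"},
               {"name": "Bilateral AP Hands", "chart": "Hands AP"}],
     "bands": null},
    {"exam": "Skeletal Survey - Bone Dysplasia",
     "views": [{"name": "Skull AP", "chart": "Skull AP/Lateral/Townes"},
               {"name": "Skull Lateral", "chart": "Skull AP/Lateral/Townes"},
               {"name": "AP Chest (for ribs)", "chart": "Chest AP for Ribs"},
               {"name": "AP Abdomen incl. Pelvis", "chart": "Abdomen AP (including pelvis)"},
               {"name": "Lateral Spine", "chart": "Lateral Spine Lateral"},
               {"name": "Bilateral AP Femur", "chart": "Femur Bilateral AP"},
               {"name": "Bilateral AP Tibia/Fibula", "chart": "Tibia/Fibula AP/Lateral (including bilateral)"},
               {"name": "Bilateral Feet", "chart": "Foot AP/Oblique/Lateral"},
               {"name": "AP Humerus", "chart": "Humerus AP"},
               {"name": "Bilateral AP Forearms", "chart": "Forearm AP"},
               {"name": "AP Hand", "chart": "Hands AP"}],
     "bands": null}
  ]
}
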