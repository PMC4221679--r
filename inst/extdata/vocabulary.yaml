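# Canonical questionnaire vocabulary, version 1.
#
# The silhouette is divided into 16 body areas. The published coding only
# consumes region-group membership (upper body / upper limb / lower limb),
# so the area list itself is a package convention; the region tags are what
# carry the scoring semantics. Trunk areas are tagged TRUNK_OTHER and feed
# no coded item.
version: 1
body_areas:
  - {code: HEAD,           region: UPPER_BODY}
  - {code: NECK,           region: UPPER_BODY}
  - {code: SHOULDER_LEFT,  region: UPPER_BODY}
  - {code: SHOULDER_RIGHT, region: UPPER_BODY}
  - {code: ARM_LEFT,       region: UPPER_LIMB}
  - {code: ARM_RIGHT,      region: UPPER_LIMB}
  - {code: HAND_LEFT,      region: UPPER_LIMB}
  - {code: HAND_RIGHT,     region: UPPER_LIMB}
  - {code: CHEST,          region: TRUNK_OTHER}
  - {code: ABDOMEN,        region: TRUNK_OTHER}
  - {code: UPPER_BACK,     region: TRUNK_OTHER}
  - {code: LOWER_BACK,     region: TRUNK_OTHER}
  - {code: LEG_LEFT,       region: LOWER_LIMB}
  - {code: LEG_RIGHT,      region: LOWER_LIMB}
  - {code: FOOT_LEFT,      region: LOWER_LIMB}
  - {code: FOOT_RIGHT,     region: LOWER_LIMB}
# The 8 kinds of pain offered by the pain-description question.
pain_descriptors:
  - MUSCLE_ACHES
  - CRAMPS
  - PINS_AND_NEEDLES
  - STABBING
  - SHOOTING
  - BURNING
  - PULLING
  - MOVING_PAIN
# The 17 associated symptoms offered by the symptom checklist.
symptoms:
  - STIFFNESS
  - HEADACHES
  - TIREDNESS
  - TIRED_ON_WAKING
  - EXHAUSTION
  - INSOMNIA
  - DISRUPTED_SLEEP
  - SENSITIVE_COLD_HEAT
  - SENSITIVE_SMELLS
  - SENSITIVE_NOISE
  - SENSITIVE_TOUCH
  - MEMORY_PROBLEMS
  - CONCENTRATION_PROBLEMS
  - NAUSEA
  - DIARRHOEA
  - CONSTIPATION
  - URINATION_PROBLEMS
ordinals:
  q2_pain_freq:   [EVERY_DAY, ALMOST_EVERY_DAY, SOME_DAYS]
  q4_tired_freq:  [EVERY_DAY, SOME_DAYS, NEVER]
  q5_effort:      [MUCH_MORE, SLIGHTLY_MORE, NO_DIFFERENCE]
  q13_recognition: [ABSOLUTELY, A_LITTLE, NOT_AT_ALL]
labels: [ACR_POS, ACR_NEG, FM, NON_FM]
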