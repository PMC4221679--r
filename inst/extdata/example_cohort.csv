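respondent_id,label,q1_areas,q2_pain_freq,q3_pain_kinds,q4_tired_freq,q5_effort,q6_symptoms,q7_q12,q13_recognition,q14_text
fm_001,FM,NECK;SHOULDER_RIGHT;ARM_RIGHT;HAND_RIGHT;FOOT_LEFT;FOOT_RIGHT;CHEST,SOME_DAYS,SHOOTING;STABBING;CRAMPS;BURNING;MUSCLE_ACHES,EVERY_DAY,MUCH_MORE,DIARRHOEA;NAUSEA;MEMORY_PROBLEMS;EXHAUSTION;SENSITIVE_SMELLS;TIREDNESS;TIRED_ON_WAKING;CONCENTRATION_PROBLEMS;DISRUPTED_SLEEP;SENSITIVE_TOUCH;INSOMNIA;CONSTIPATION;URINATION_PROBLEMS;HEADACHES;STIFFNESS;SENSITIVE_NOISE;SENSITIVE_COLD_HEAT,,A_LITTLE,
fm_002,FM,SHOULDER_RIGHT;SHOULDER_LEFT;HAND_LEFT;HAND_RIGHT;ARM_LEFT;LEG_RIGHT;LEG_LEFT;FOOT_RIGHT;UPPER_BACK;CHEST,EVERY_DAY,MUSCLE_ACHES;MOVING_PAIN;PULLING;STABBING;PINS_AND_NEEDLES;CRAMPS;BURNING;SHOOTING,EVERY_DAY,MUCH_MORE,STIFFNESS;SENSITIVE_COLD_HEAT;MEMORY_PROBLEMS;SENSITIVE_NOISE;TIRED_ON_WAKING;DISRUPTED_SLEEP;SENSITIVE_SMELLS;DIARRHOEA;NAUSEA;EXHAUSTION;CONCENTRATION_PROBLEMS;INSOMNIA;URINATION_PROBLEMS;TIREDNESS;SENSITIVE_TOUCH;CONSTIPATION;HEADACHES,,ABSOLUTELY,
nonfm_001,NON_FM,HEAD;CHEST,ALMOST_EVERY_DAY,CRAMPS;MOVING_PAIN;SHOOTING;PINS_AND_NEEDLES;BURNING;PULLING;STABBING,EVERY_DAY,MUCH_MORE,TIREDNESS;MEMORY_PROBLEMS;DIARRHOEA;TIRED_ON_WAKING;SENSITIVE_SMELLS;INSOMNIA,,NOT_AT_ALL,
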