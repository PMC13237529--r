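symptom_tier_map:
  temperature:
  - GREEN
  - GREEN
  - AMBER
  - RED
  dyspnea:
  - GREEN
  - GREEN
  - AMBER
  - RED
  nausea_vomiting:
  - GREEN
  - GREEN
  - AMBER
  - RED
  diarrhea:
  - GREEN
  - GREEN
  - AMBER
  - RED
  constipation:
  - GREEN
  - GREEN
  - AMBER
  - RED
  pain:
  - GREEN
  - GREEN
  - AMBER
  - RED
  bleeding_bruising:
  - GREEN
  - GREEN
  - AMBER
  - RED
  fatigue:
  - GREEN
  - GREEN
  - AMBER
  - RED
  skin_rash:
  - GREEN
  - GREEN
  - AMBER
  - RED
  peripheral_neuropathy:
  - GREEN
  - GREEN
  - AMBER
  - RED
  oral_mucositis:
  - GREEN
  - GREEN
  - AMBER
  - RED
multi_amber_upgrade: yes
multi_amber_threshold: 2
domain_map:
  temperature: fever_temperature
  dyspnea: respiratory
  nausea_vomiting: gastrointestinal
  diarrhea: gastrointestinal
  constipation: gastrointestinal
  pain: pain
  bleeding_bruising: bleeding_bruising
  fatigue: fatigue_wellbeing
  skin_rash: skin
  peripheral_neuropathy: neuropathy
  oral_mucositis: mucositis
schedule:
  staffed_weekdays:
  - 1
  - 2
  - 3
  - 4
  - 5
  start: '09:00'
  end: '17:00'
  timezone: Europe/London
episode_window_hours: 48.0
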